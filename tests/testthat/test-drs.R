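# Diffuse reflectance indices: optical density, landmark sampling, the
# chromophore formulas, the linearity fit and healthy-skin normalization.

test_that("optical density is -log10 reflectance and inverts exactly", {
  sp <- make_spectrum(function(wl) rep(0.1, length(wl)))
  od <- optical_density(sp)
  expect_equal(od$od, rep(1, nrow(od)))
  expect_equal(optical_density(make_spectrum(function(wl) rep(1, length(wl))))$od,
               rep(0, 251))
  # specific value and round trip
  sp2 <- make_spectrum(function(wl) 0.2 + 0.6 * (wl - 450) / 500)
  od2 <- optical_density(sp2)
  expect_equal(od_at(od2, 620), -log10(0.2 + 0.6 * 170 / 500), tolerance = 1e-12)
  expect_equal(10^(-od2$od), sp2$reflectance, tolerance = 1e-12)
  expect_error(optical_density(tibble::tibble(wavelength_nm = c(500, 600),
                                              reflectance = c(0.5, 0))),
               class = "dermofuse_invalid_spectrum")
})

test_that("od_at interpolates linearly and rejects out-of-range queries", {
  od <- tibble::tibble(wavelength_nm = c(600, 610, 620, 640),
                       od = c(0.15, 0.1, 0.3, 0.6))
  expect_equal(od_at(od, 620), 0.3)                # on-grid identity
  expect_equal(od_at(od, 630), 0.45)               # midpoint
  expect_equal(od_at(od, 612.5), 0.15)             # quarter point of 610-620
  expect_error(od_at(od, 500), class = "dermofuse_range_error")
})

test_that("melanin index is 100 (OD620 - OD700) with antisymmetry", {
  flat <- optical_density(make_spectrum(function(wl) rep(0.35, length(wl))))
  expect_equal(melanin_index(flat), 0)
  step <- function(r620, r700) {
    optical_density(make_spectrum(function(wl)
      ifelse(wl < 660, r620, r700)))
  }
  expect_equal(melanin_index(step(0.4, 0.5)), 100 * (-log10(0.4) + log10(0.5)),
               tolerance = 1e-9)
  expect_equal(melanin_index(step(0.5, 0.4)), -melanin_index(step(0.4, 0.5)),
               tolerance = 1e-9)
})

test_that("erythema index uses the Dawson grouping", {
  flat <- optical_density(make_spectrum(function(wl) rep(0.6, length(wl))))
  expect_equal(erythema_index(flat), 0, tolerance = 1e-12)
  # piecewise OD: 0.1 at the flanks (510/610), 0.3 at the peaks (545/560/575)
  odfun <- function(wl) ifelse(wl >= 530 & wl <= 590, 0.3, 0.1)
  sp <- make_spectrum(function(wl) 10^(-odfun(wl)), wl = seq(450, 950, 1))
  expect_equal(erythema_index(optical_density(sp)),
               100 * (0.3 + 1.5 * 0.6 - 2 * 0.2), tolerance = 1e-9)
  # linearity: doubling OD doubles E
  sp2 <- make_spectrum(function(wl) 10^(-2 * odfun(wl)), wl = seq(450, 950, 1))
  expect_equal(erythema_index(optical_density(sp2)),
               2 * erythema_index(optical_density(sp)), tolerance = 1e-9)
  # affine OD contributes nothing (coefficients sum to zero with zero moment)
  aff <- optical_density(make_spectrum(function(wl) 10^(-(0.1 + 1e-3 * wl))))
  expect_equal(erythema_index(aff), 0, tolerance = 1e-9)
})

test_that("hemoglobin index is the 529/545/570 curvature contrast", {
  flat <- optical_density(make_spectrum(function(wl) rep(0.4, length(wl))))
  expect_equal(hemoglobin_index(flat), 0)
  odfun <- function(wl) ifelse(abs(wl - 529) < 1, 0.1,
                        ifelse(abs(wl - 545) < 1, 0.42,
                        ifelse(abs(wl - 570) < 1, 0.17, 0.2)))
  sp <- make_spectrum(function(wl) 10^(-odfun(wl)), wl = seq(450, 950, 1))
  expect_equal(hemoglobin_index(optical_density(sp)),
               0.32 / 16 + 0.25 / 25, tolerance = 1e-9)
  # adding a constant OD leaves H unchanged
  sp2 <- make_spectrum(function(wl) 10^(-(odfun(wl) + 0.25)), wl = seq(450, 950, 1))
  expect_equal(hemoglobin_index(optical_density(sp2)),
               hemoglobin_index(optical_density(sp)), tolerance = 1e-9)
})

test_that("linearity fit recovers slope and RMS residual in 650-800 nm", {
  lin <- make_spectrum(function(wl) 0.25 + 0.001 * (wl - 650))
  fit <- reflectance_linearity(lin)
  expect_equal(fit$linearity, 0.001, tolerance = 1e-12)
  expect_equal(fit$error_linearity, 0, tolerance = 1e-10)
  const <- reflectance_linearity(make_spectrum(function(wl) rep(0.4, length(wl))))
  expect_equal(const$linearity, 0, tolerance = 1e-12)
  expect_equal(const$error_linearity, 0, tolerance = 1e-12)
  # alternating +/- 0.01 perturbation on an even count of points keeps the
  # slope and gives RMS exactly 0.01
  wl <- seq(650, 800, by = 2)  # 76 points
  pert <- rep(c(0.01, -0.01), length.out = length(wl))
  sp <- tibble::tibble(wavelength_nm = wl,
                       reflectance = 0.2 + 0.001 * (wl - 650) + pert)
  fit2 <- reflectance_linearity(sp)
  o <- brute_ols(wl, sp$reflectance)
  expect_equal(fit2$linearity, o$slope, tolerance = 1e-10)
  expect_equal(fit2$error_linearity, o$rms, tolerance = 1e-10)
  expect_lt(abs(fit2$error_linearity - 0.01), 1e-3)
  expect_error(reflectance_linearity(
    tibble::tibble(wavelength_nm = c(500, 660, 900),
                   reflectance = c(0.4, 0.4, 0.4))),
    class = "dermofuse_insufficient_data")
})

test_that("linearity fit matches the normal-equation oracle on random spectra", {
  withr::with_seed(7, {
    for (i in 1:20) {
      wl <- sort(runif(20, 650, 800))
      r <- runif(20, 0.1, 0.9)
      sp <- tibble::tibble(wavelength_nm = wl, reflectance = r)
      fit <- reflectance_linearity(sp)
      o <- brute_ols(wl, r)
      expect_equal(fit$linearity, o$slope, tolerance = 1e-10)
      expect_equal(fit$error_linearity, o$rms, tolerance = 1e-10)
    }
  })
})

test_that("malignancy coefficient obeys its ratio algebra", {
  a <- make_spectrum(function(wl) 0.2 + 0.4 * (wl - 450) / 500)
  b <- make_spectrum(function(wl) 0.5 - 0.2 * (wl - 450) / 500)
  expect_equal(malignancy_coefficient(a, a), 1, tolerance = 1e-12)
  expect_equal(malignancy_coefficient(a, b) * malignancy_coefficient(b, a), 1,
               tolerance = 1e-12)
  # direct arithmetic: Rh500=0.2, Rh700=0.4, Rn500=0.1, Rn700=0.4
  h <- make_spectrum(function(wl) ifelse(wl < 600, 0.2, 0.4))
  n <- make_spectrum(function(wl) ifelse(wl < 600, 0.1, 0.4))
  expect_equal(malignancy_coefficient(n, h), 2.0, tolerance = 1e-12)
})

test_that("drs_features normalizes to healthy means and guards division", {
  # spectrum with melanin ramp + hemoglobin dips so every coefficient is
  # nonzero for the healthy reference
  mk <- function(m) make_spectrum(function(wl)
    10^(-(0.3 + (m / 100) * pmin(pmax((700 - wl) / 80, -1.25), 2.5) +
            0.05 * (exp(-(wl - 545)^2 / 200) + exp(-(wl - 575)^2 / 200)))))
  lesion <- mk(2); healthy <- mk(2)
  # identical spectra: all normalized ratios 1, Rt 1
  out <- drs_features(list(lesion, lesion), list(healthy, healthy))
  expect_equal(nrow(out), 2)
  expect_equal(out$M, c(1, 1), tolerance = 1e-9)
  expect_equal(out$Linearity, c(1, 1), tolerance = 1e-9)
  expect_equal(out$Rt, c(1, 1), tolerance = 1e-9)
  # 10 lesion spectra in -> 10 rows out
  out10 <- drs_features(rep(list(lesion), 10), list(healthy))
  expect_equal(nrow(out10), 10)
  expect_equal(out10$obs_idx, 1:10)
  # healthy M means 4 and 6 (dips contribute ~0 at 620/700) -> lesion M = 10
  # scales to ~2
  out2 <- drs_features(list(mk(10)), list(mk(4), mk(6)))
  expect_equal(out2$M, 2, tolerance = 1e-3)
  # flat healthy spectra have zero M/E/H -> named division guard
  flat <- make_spectrum(function(wl) rep(0.5, length(wl)))
  expect_error(drs_features(list(lesion), list(flat)),
               class = "dermofuse_division_guard")
})

test_that("scaling all reflectances leaves E, H and Rt unchanged", {
  withr::with_seed(3, {
    base <- make_spectrum(function(wl)
      0.3 + 0.2 * sin(wl / 40) + 0.1 * (wl - 450) / 500)
    scaled <- base; scaled$reflectance <- scaled$reflectance * 1.7
    for (pair in list(list(base, scaled))) {
      e1 <- erythema_index(optical_density(pair[[1]]))
      e2 <- erythema_index(optical_density(pair[[2]]))
      expect_equal(e1, e2, tolerance = 1e-9)
      h1 <- hemoglobin_index(optical_density(pair[[1]]))
      h2 <- hemoglobin_index(optical_density(pair[[2]]))
      expect_equal(h1, h2, tolerance = 1e-9)
    }
    other <- make_spectrum(function(wl) 0.5 - 0.1 * (wl - 450) / 500)
    other_s <- other; other_s$reflectance <- other_s$reflectance * 1.7
    expect_equal(malignancy_coefficient(base, other),
                 malignancy_coefficient(scaled, other_s), tolerance = 1e-12)
  })
})
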