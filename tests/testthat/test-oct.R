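# OCT texture pipeline: thresholding, denoising chain, first-order
# statistics, Shannon entropy, GLCM construction and Haralick features.

test_that("background threshold is mean plus population sd", {
  px <- matrix(5L, 20, 20)
  sc <- tiny_bscan(px)
  region <- texture_roi(1, 1, 20, 20)
  expect_equal(background_threshold(sc, region), 5)
  px2 <- matrix(c(3L, 7L), 20, 20)
  expect_equal(background_threshold(tiny_bscan(px2), region), 7) # mean 5, sd 2
  withr::with_seed(5, {
    vals <- sample(0:40, 1000, replace = TRUE, prob = stats::dpois(0:40, 12))
    px3 <- matrix(as.integer(vals), 25, 40)
    m <- mean(vals); s <- sqrt(mean((vals - m)^2))
    expect_equal(background_threshold(tiny_bscan(px3), texture_roi(1, 1, 25, 40)),
                 m + s, tolerance = 1e-9)
  })
})

test_that("threshold filter zeroes at-or-below and keeps above", {
  px <- matrix(c(10L, 20L, 30L, 40L), 2, 2)
  out <- threshold_filter(tiny_bscan(px), 20)
  expect_equal(as.integer(out), c(0L, 0L, 30L, 40L))
  expect_equal(as.integer(threshold_filter(tiny_bscan(px), 255)), rep(0L, 4))
  # threshold 0 only kills exact zeros
  px0 <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  expect_equal(as.integer(threshold_filter(tiny_bscan(px0), 0)),
               c(0L, 1L, 2L, 3L))
})

test_that("denoising is erosion then Gaussian smoothing, checked against
          brute-force composition on the interior", {
  # constant image is a fixed point (up to rounding)
  const <- tiny_bscan(matrix(100L, 30, 30))
  expect_equal(as.integer(denoise_bscan(const)), rep(100L, 900))
  # isolated bright pixel is removed by the minimum filter
  spike <- matrix(0L, 30, 30); spike[15, 15] <- 200L
  expect_true(all(as.integer(denoise_bscan(tiny_bscan(spike))) == 0L))
  # seeded random image: interior equals min-filter + direct convolution
  withr::with_seed(11, {
    px <- matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40)
    out <- denoise_bscan(tiny_bscan(px))
    er <- brute_min_filter(px / 255)
    sm <- brute_gaussian(er, sigma = 1.5, radius = 13)
    expected <- round(sm * 255)
    interior <- !is.na(expected)
    expect_true(all(abs(unclass(out)[interior] - expected[interior]) <= 1))
  })
})

test_that("first-order statistics are population moments over nonzero pixels", {
  px <- matrix(0L, 4, 4)
  px[1, 1:4] <- c(1L, 2L, 3L, 4L)
  sc <- tiny_bscan(px)
  roi <- texture_roi(1, 1, 4, 4)
  fos <- first_order_stats(sc, roi)
  expect_equal(fos$fos_mean, 2.5)
  expect_equal(fos$fos_skewness, 0)
  expect_equal(fos$fos_std, sqrt(1.25), tolerance = 1e-12)   # ~1.1180
  expect_equal(fos$fos_kurtosis, 1.64, tolerance = 1e-12)    # non-excess
  # oracle agreement on a random ROI
  withr::with_seed(2, {
    px2 <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    o <- brute_population_stats(px2[px2 > 0])
    fos2 <- first_order_stats(tiny_bscan(px2), texture_roi(1, 1, 10, 10))
    expect_equal(fos2$fos_mean, o$mean, tolerance = 1e-12)
    expect_equal(fos2$fos_std, o$sd, tolerance = 1e-12)
    expect_equal(fos2$fos_skewness, o$skewness, tolerance = 1e-12)
    expect_equal(fos2$fos_kurtosis, o$kurtosis, tolerance = 1e-12)
  })
  # degenerate cases
  expect_error(first_order_stats(tiny_bscan(matrix(0L, 4, 4)),
                                 texture_roi(1, 1, 4, 4)),
               class = "dermofuse_degenerate_roi")
  expect_warning(
    z <- first_order_stats(tiny_bscan(matrix(7L, 4, 4)), texture_roi(1, 1, 4, 4)),
    "zero-variance")
  expect_equal(c(z$fos_skewness, z$fos_kurtosis), c(0, 0))
})

test_that("Shannon entropy in bits over the nonzero gray-level histogram", {
  roi <- texture_roi(1, 1, 4, 4)
  expect_equal(shannon_entropy(tiny_bscan(matrix(9L, 4, 4)), roi), 0)
  two <- matrix(c(3L, 5L), 4, 4)
  expect_equal(shannon_entropy(tiny_bscan(two), roi), 1)
  # frequencies 1/2, 1/4, 1/8, 1/8 -> 1.75 bits
  v <- c(rep(1L, 8), rep(2L, 4), rep(3L, 2), rep(4L, 2))
  expect_equal(shannon_entropy(tiny_bscan(matrix(v, 4, 4)), roi), 1.75)
  # zero pixels excluded: padding with zeros changes nothing
  pad <- matrix(0L, 8, 8); pad[1:4, 1:4] <- matrix(v, 4, 4)
  expect_equal(shannon_entropy(tiny_bscan(pad), texture_roi(1, 1, 8, 8)), 1.75)
})

test_that("GLCM matches hand-computed examples and is symmetric-normalized", {
  # constant ROI: single diagonal entry 1
  g <- glcm(tiny_bscan(matrix(50L, 6, 6)), texture_roi(1, 1, 6, 6), 0, 1)
  expect_equal(sum(g), 1)
  expect_equal(g[51, 51], 1)
  # 2x2 image [[1,1],[2,2]] (rows), horizontal d=1: p(1,1)=p(2,2)=0.5
  px <- rbind(c(1L, 1L), c(2L, 2L))
  g2 <- glcm(tiny_bscan(px), texture_roi(1, 1, 2, 2), 0, 1)
  expect_equal(g2[2, 2], 0.5)
  expect_equal(g2[3, 3], 0.5)
  # no valid pairs -> error naming the offset
  expect_error(glcm(tiny_bscan(matrix(1L, 2, 2)), texture_roi(1, 1, 2, 2), 0, 5),
               class = "dermofuse_invalid_glcm")
  # zero pixels excluded from pairs
  pxz <- rbind(c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L))
  gz <- glcm(tiny_bscan(pxz), texture_roi(1, 1, 3, 3), 0, 1)
  expect_equal(gz[2, 2], 1)  # only the (2,1)-(2,2),(2,2)-(2,3) row pairs count
})

test_that("GLCM equals the brute-force pair-enumeration oracle on 50+ seeded ROIs", {
  withr::with_seed(99, {
    for (i in 1:50) {
      n <- sample(8:16, 1); m <- sample(8:16, 1)
      px <- matrix(sample(0:12, n * m, replace = TRUE), n, m) * 20L
      sc <- tiny_bscan(px)
      roi <- texture_roi(1, 1, n, m)
      for (a in c(0, 45, 90, 135)) {
        for (d in c(1, 5, 9)) {
          skip <- (d >= n && a != 0) || (d >= m && a != 90)
          if (skip) next
          got <- glcm(sc, roi, a, d)
          ref <- brute_glcm(px, list(row = 1, col = 1, height = n, width = m),
                            a, d)
          expect_equal(unclass(got), ref, ignore_attr = TRUE,
                       tolerance = 1e-12)
          expect_equal(sum(got), 1, tolerance = 1e-9)
          expect_equal(unclass(got), t(unclass(got)), ignore_attr = TRUE)
        }
      }
    }
  })
})

test_that("down-quantized GLCMs (32 levels) match the oracle too", {
  withr::with_seed(41, {
    px <- matrix(sample(0:255, 144, replace = TRUE), 12, 12)
    sc <- tiny_bscan(px)
    roi <- texture_roi(1, 1, 12, 12)
    for (a in c(0, 90)) {
      g <- glcm(sc, roi, a, 1, levels = 32)
      expect_equal(dim(g), c(32L, 32L))
      ref <- brute_glcm(px, list(row = 1, col = 1, height = 12, width = 12),
                        a, 1, levels = 32)
      expect_equal(unclass(g), ref, ignore_attr = TRUE, tolerance = 1e-12)
    }
  })
})

test_that("Haralick features match direct substitution on small matrices", {
  mk <- function(entries) {
    p <- matrix(0, 4, 4)
    for (e in entries) p[e[1] + 1, e[2] + 1] <- e[3]
    structure(p, class = c("glcm", "matrix"))
  }
  # single diagonal entry: degenerate case by definition
  h1 <- haralick_features(mk(list(c(2, 2, 1))))
  expect_equal(unlist(h1),
               c(energy = 1, contrast = 0, correlation = 1, entropy = 0,
                 homogeneity = 1))
  # p(0,0)=p(1,1)=0.5: perfect correlation, 1 bit entropy
  h2 <- haralick_features(mk(list(c(0, 0, 0.5), c(1, 1, 0.5))))
  expect_equal(unlist(h2),
               c(energy = 0.5, contrast = 0, correlation = 1, entropy = 1,
                 homogeneity = 1))
  # p(0,1)=p(1,0)=0.5: perfect anti-correlation, contrast 1
  h3 <- haralick_features(mk(list(c(0, 1, 0.5), c(1, 0, 0.5))))
  expect_equal(h3$contrast, 1)
  expect_equal(h3$correlation, -1)
  expect_equal(h3$homogeneity, 0.5)
  # unnormalized matrix rejected
  expect_error(haralick_features(mk(list(c(0, 0, 0.7)))),
               class = "dermofuse_invalid_glcm")
})

test_that("gray-level shift leaves second-order features unchanged, moves mean", {
  withr::with_seed(21, {
    px <- matrix(sample(40:120, 144, replace = TRUE), 12, 12)
    sc1 <- tiny_bscan(px)
    sc2 <- tiny_bscan(px + 60L)
    roi <- texture_roi(1, 1, 12, 12)
    f1 <- first_order_stats(sc1, roi); f2 <- first_order_stats(sc2, roi)
    expect_equal(f2$fos_mean, f1$fos_mean + 60)
    expect_equal(f2$fos_std, f1$fos_std, tolerance = 1e-12)
    for (a in c(0, 90)) {
      h1 <- haralick_features(glcm(sc1, roi, a, 1))
      h2 <- haralick_features(glcm(sc2, roi, a, 1))
      expect_equal(h1$contrast, h2$contrast, tolerance = 1e-12)
      expect_equal(h1$homogeneity, h2$homogeneity, tolerance = 1e-12)
      expect_equal(h1$correlation, h2$correlation, tolerance = 1e-9)
      expect_equal(h1$entropy, h2$entropy, tolerance = 1e-12)
    }
  })
})

test_that("contrast at d=1 falls as the texture correlation length grows", {
  withr::with_seed(31, {
    lens <- c(1, 2, 3.5, 5.5, 8)
    contr <- vapply(lens, function(L) {
      p <- tibble::tibble(mean_intensity = 128,
                          texture_correlation_length_px = L,
                          texture_contrast = 40)
      vals <- replicate(3, {
        o <- generate_bscan(p)
        thr <- background_threshold(o$scan, o$background)
        den <- denoise_bscan(threshold_filter(o$scan, thr))
        haralick_features(glcm(den, o$roi, 0, 1))$contrast
      })
      mean(vals)
    }, numeric(1))
    expect_lt(stats::cor(lens, contr, method = "spearman"), 0)
    # the extreme lengths must separate clearly even at few replicates
    expect_lt(contr[length(contr)], contr[1])
  })
})

test_that("the full OCT feature vector has 65 named values in schema order", {
  cfg <- glcm_config()
  nm <- oct_feature_names(cfg)
  expect_length(nm, 65)
  expect_false(any(duplicated(nm)))
  withr::with_seed(8, {
    p <- tibble::tibble(mean_intensity = 120,
                        texture_correlation_length_px = 3,
                        texture_contrast = 30)
    o <- generate_bscan(p)
    row <- oct_features(o$scan, o$roi, o$background, cfg)
    expect_equal(names(row), nm)
    expect_equal(ncol(row), 65)
    # field-by-field equality with an independently scripted stage-wise rerun
    thr <- background_threshold(o$scan, o$background)
    den <- denoise_bscan(threshold_filter(o$scan, thr))
    expect_equal(row$shannon_entropy, shannon_entropy(o$scan, o$roi))
    expect_equal(row$fos_mean, first_order_stats(den, o$roi)$fos_mean)
    ref <- brute_glcm(unclass(den), o$roi, 45, 5)
    h <- haralick_features(structure(ref, class = c("glcm", "matrix")))
    expect_equal(row$contrast_a45_d5, h$contrast, tolerance = 1e-12)
    expect_equal(row$energy_a45_d5, h$energy, tolerance = 1e-12)
  })
  # constant nonzero ROI: all 12 energies 1, all contrasts 0
  g <- bscan_layout <- dermofuse:::bscan_layout()
  px <- matrix(0L, g$nrow, g$ncol)
  px[1:g$tissue_rows, ] <- 99L
  px[dermofuse:::roi_rows(g$background), dermofuse:::roi_cols(g$background)] <- 4L
  sc <- bscan(px, g$axial_pitch_um, g$lateral_pitch_um)
  expect_warning(row <- oct_features(sc, g$roi, g$background, cfg),
                 "zero-variance")
  expect_true(all(unlist(row[grep("^energy_", names(row))]) == 1))
  expect_true(all(unlist(row[grep("^contrast_", names(row))]) == 0))
  expect_equal(row$shannon_entropy, 0)
})

test_that("ROI extent rule enforces the physical minimum window", {
  px <- matrix(10L, 200, 100)
  sc <- bscan(px, axial_pitch_um = 5.34, lateral_pitch_um = 7.32)
  expect_silent(validate_roi_extent(sc, texture_roi(1, 1, 101, 56)))
  expect_error(validate_roi_extent(sc, texture_roi(1, 1, 99, 56)),
               class = "dermofuse_invalid_roi")
  expect_error(validate_roi_extent(sc, texture_roi(1, 1, 101, 54)),
               class = "dermofuse_invalid_roi")
  expect_error(validate_roi_extent(sc, texture_roi(150, 1, 101, 56)),
               class = "dermofuse_invalid_roi")
})
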