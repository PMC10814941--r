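#' Synthetic multimodal cohort generator
#'
#' Seeded, phenomenological emulation of the three input modalities with
#' class-dependent structure: reflectance spectra built from a constant
#' optical-density baseline plus a melanin ramp, oxyhemoglobin Gaussian dips
#' and a near-infrared slope; OCT B-scans as Gaussian random fields with a
#' class-specific correlation length and contrast over a noise background
#' strip; and ultrasound annotator mask pairs as randomly oriented ellipses
#' with smooth radial boundary roughness. The generator targets the
#' downstream features (landmark optical densities, GLCM statistics, shape
#' moments), not tissue physics.
#'
#' All generators draw from R's ambient RNG stream; seed with `set.seed()`
#' or use the cohort-level entry points, which seed deterministically.
#'
#' @name synthetic
NULL

# fixed healthy-skin baseline (all classes share it)
.HEALTHY <- list(melanin_slope = 0.03, hemoglobin_dip_depth = 0.05,
                 nir_slope = 1.5e-4)

# melanin shape: OD(620) - OD(700) difference is exactly 1, clamped outside
# [500, 800] nm so reflectance stays in range at high melanin
mel_shape <- function(wl) pmin(pmax((700 - wl) / 80, -1.25), 2.5)

#' Generate one reflectance spectrum
#'
#' @param params One-row parameter set (a [class_params()] row) with
#'   `melanin_slope`, `hemoglobin_dip_depth`, `nir_slope`, `noise_sd_drs`.
#' @param site `"lesion"` uses the class parameters; `"healthy"` uses the
#'   shared healthy-skin baseline (with the same noise level).
#' @param wavelengths_nm Spectral grid.
#' @return A spectrum tibble (`wavelength_nm`, `reflectance`).
#' @export
generate_spectrum <- function(params, site = c("lesion", "healthy"),
                              wavelengths_nm = 450:950) {
  site <- match.arg(site)
  wl <- wavelengths_nm
  p <- if (site == "healthy") c(.HEALTHY, noise_sd_drs = params$noise_sd_drs)
       else params
  dip <- exp(-(wl - 545)^2 / 200) + exp(-(wl - 575)^2 / 200)
  od <- 0.30 + p$melanin_slope * mel_shape(wl) + p$hemoglobin_dip_depth * dip
  r <- 10^(-od) * (1 + p$nir_slope * (wl - 700))
  r <- r + stats::rnorm(length(wl), 0, p$noise_sd_drs)
  if (any(r >= 1.5)) {
    rlang::abort("generator parameters produced reflectance >= 1.5",
                 class = "dermofuse_generator_error")
  }
  r <- pmax(r, 1e-3)
  tibble::tibble(wavelength_nm = wl, reflectance = r)
}

# B-scan geometry shared by generator and manifests
bscan_layout <- function() {
  list(nrow = 190L, ncol = 90L, tissue_rows = 148L,
       roi = texture_roi(21, 18, 101, 56),
       background = texture_roi(153, 5, 36, 82),
       axial_pitch_um = 5.34, lateral_pitch_um = 7.32)
}

#' Generate one OCT B-scan with its analysis regions
#'
#' The tissue block is a Gaussian random field (white noise smoothed with a
#' Gaussian kernel of the class's correlation length, rescaled to the
#' class's contrast and shifted to its mean intensity); a pure-noise
#' background strip sits below it. The fixed ROI spans 101 x 56 px = 539 x
#' 410 um at the declared 5.34 / 7.32 um pitch.
#'
#' @param params One-row parameter set with `mean_intensity`,
#'   `texture_correlation_length_px`, `texture_contrast`.
#' @return List `scan` ([bscan()]), `roi`, `background`
#'   ([texture_roi()]s).
#' @export
generate_bscan <- function(params) {
  g <- bscan_layout()
  img <- matrix(0L, g$nrow, g$ncol)
  field <- matrix(stats::rnorm(g$tissue_rows * g$ncol), g$tissue_rows, g$ncol)
  if (params$texture_contrast > 0 &&
      params$texture_correlation_length_px > 0.5) {
    field <- EBImage::gblur(field, sigma = params$texture_correlation_length_px)
  }
  s <- stats::sd(field)
  field <- if (s > 0) field / s * params$texture_contrast else field * 0
  tissue <- round(params$mean_intensity + field)
  img[seq_len(g$tissue_rows), ] <- pmin(pmax(tissue, 1), 255)
  bg <- round(abs(stats::rnorm(g$background$height * g$background$width, 5, 2)))
  img[roi_rows(g$background), roi_cols(g$background)] <-
    pmin(pmax(bg, 0), 255)
  list(scan = bscan(img, g$axial_pitch_um, g$lateral_pitch_um),
       roi = g$roi, background = g$background)
}

# smooth radial perturbation: low-order Fourier series with 1/k decay
radial_perturbation <- function(theta, amplitude, harmonics = 2:5) {
  if (amplitude <= 0) return(rep(0, length(theta)))
  out <- rep(0, length(theta))
  for (k in harmonics) {
    out <- out + stats::rnorm(1, 0, 1 / k) * cos(k * theta) +
      stats::rnorm(1, 0, 1 / k) * sin(k * theta)
  }
  amplitude * out
}

#' Generate a two-annotator ultrasound mask pair
#'
#' A base ellipse with the class's eccentricity and equivalent diameter,
#' rotated at random, with a shared smooth radial boundary perturbation;
#' each annotator adds an independent small radial disagreement. The
#' intersection is nonempty by construction (perturbations are small
#' relative to the lesion radius).
#'
#' @param params One-row parameter set with `shape_eccentricity`,
#'   `boundary_roughness`, `size_mm`, `annotator_jitter`.
#' @param grid_px Mask grid side length.
#' @param spacing_mm Pixel spacing (row, col) in mm.
#' @return List `mask_a`, `mask_b` ([roi_mask()]s).
#' @export
generate_mask_pair <- function(params, grid_px = 128L,
                               spacing_mm = c(0.1, 0.1)) {
  e <- min(max(params$shape_eccentricity, 0), 0.9)
  d <- params$size_mm
  if (d <= 0.5) {
    rlang::abort("degenerate lesion size", class = "dermofuse_generator_error")
  }
  a <- (d / 2) / (1 - e^2)^0.25          # semi-axes with a*b = (d/2)^2
  b <- (d / 2) * (1 - e^2)^0.25
  phi <- stats::runif(1, -pi / 2, pi / 2)
  ctr <- (grid_px + 1) / 2
  x <- (matrix(rep(seq_len(grid_px), each = grid_px), grid_px) - ctr) * spacing_mm[2]
  y <- (matrix(rep(seq_len(grid_px), times = grid_px), grid_px) - ctr) * spacing_mm[1]
  u <- (x * cos(phi) + y * sin(phi)) / a
  v <- (-x * sin(phi) + y * cos(phi)) / b
  theta <- atan2(v, u)
  rr <- sqrt(u^2 + v^2)
  shared <- params$boundary_roughness
  jit <- params$annotator_jitter
  # one set of shared harmonics, then two independent annotator tweaks
  coef_env <- local({
    base <- radial_perturbation(as.numeric(theta), shared)
    list(base = matrix(base, grid_px, grid_px))
  })
  # the region {r <= f(theta)} with f >= 0.05 is star-shaped around the
  # center, hence connected; the consensus step re-extracts the largest
  # component anyway
  one_mask <- function() {
    own <- matrix(radial_perturbation(as.numeric(theta), jit),
                  grid_px, grid_px)
    m <- rr <= pmax(1 + coef_env$base + own, 0.05)
    roi_mask(m, spacing_mm)
  }
  list(mask_a = one_mask(), mask_b = one_mask())
}

# per-tumor random effect on the class parameters, with physical clamps
jitter_params <- function(params) {
  j <- params$tumor_jitter
  bump <- function(x) x * (1 + j * stats::rnorm(1))
  out <- params
  out$melanin_slope <- max(bump(params$melanin_slope), 0.005)
  out$hemoglobin_dip_depth <- max(bump(params$hemoglobin_dip_depth), 0.005)
  out$nir_slope <- params$nir_slope + j * 1e-4 * stats::rnorm(1)
  out$mean_intensity <- min(max(bump(params$mean_intensity), 60), 220)
  out$texture_correlation_length_px <-
    min(max(bump(params$texture_correlation_length_px), 0.8), 10)
  out$texture_contrast <- min(max(bump(params$texture_contrast), 5), 60)
  out$shape_eccentricity <- min(max(bump(params$shape_eccentricity), 0), 0.9)
  out$boundary_roughness <- min(max(bump(params$boundary_roughness), 0), 0.35)
  out$size_mm <- min(max(bump(params$size_mm), 2), 9.5)
  out
}

# raw data for one tumor (all modalities)
generate_tumor <- function(params, n_obs) {
  tumor <- jitter_params(params)
  list(
    spectra_lesion = lapply(seq_len(n_obs), function(i)
      generate_spectrum(tumor, "lesion")),
    spectra_healthy = lapply(seq_len(n_obs), function(i)
      generate_spectrum(tumor, "healthy")),
    oct = lapply(seq_len(n_obs), function(i) generate_bscan(tumor)),
    us = lapply(seq_len(n_obs), function(i) generate_mask_pair(tumor)))
}

cohort_tumor_table <- function(spec) {
  labels <- rep(names(spec$tumors_per_class), spec$tumors_per_class)
  tibble::tibble(
    tumor_id = sprintf("T%02d", seq_along(labels)),
    label = labels)
}

#' Generate a full synthetic cohort (raw data in memory)
#'
#' @param spec A [cohort_spec()].
#' @param params A [class_params()] table.
#' @return A `synthetic_cohort`: list of per-tumor raw data plus the spec
#'   and parameters. Reproducible from `spec$seed`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            params = class_params("well-separated")) {
  tumors <- cohort_tumor_table(spec)
  data <- withr::with_seed(spec$seed, {
    lapply(seq_len(nrow(tumors)), function(k) {
      p <- params[params$label == tumors$label[k], ]
      c(list(tumor_id = tumors$tumor_id[k], label = tumors$label[k]),
        generate_tumor(p, spec$observations_per_tumor))
    })
  })
  structure(list(tumors = data, spec = spec, params = params),
            class = "synthetic_cohort")
}

# feature extraction for one tumor's raw data
extract_tumor_features <- function(tum, cfg = glcm_config()) {
  drs <- drs_features(tum$spectra_lesion, tum$spectra_healthy)
  oct <- dplyr::bind_rows(lapply(seq_along(tum$oct), function(i) {
    o <- tum$oct[[i]]
    dplyr::bind_cols(tibble::tibble(obs_idx = i),
                     oct_features(o$scan, o$roi, o$background, cfg))
  }))
  us <- dplyr::bind_rows(lapply(seq_along(tum$us), function(i) {
    m <- tum$us[[i]]
    dplyr::bind_cols(tibble::tibble(obs_idx = i),
                     shape_features(consensus_roi(m$mask_a, m$mask_b)))
  }))
  lapply(list(drs = drs, oct = oct, us = us), function(tbl)
    dplyr::bind_cols(tibble::tibble(tumor_id = tum$tumor_id), tbl))
}

#' Extract all per-modality features from a cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param cfg A [glcm_config()].
#' @return List of tibbles `drs`, `oct`, `us` (each `tumor_id`, `obs_idx` +
#'   features) and `labels` (`tumor_id`, `label`).
#' @export
extract_cohort_features <- function(cohort, cfg = glcm_config()) {
  parts <- lapply(cohort$tumors, extract_tumor_features, cfg = cfg)
  list(drs = dplyr::bind_rows(lapply(parts, `[[`, "drs")),
       oct = dplyr::bind_rows(lapply(parts, `[[`, "oct")),
       us = dplyr::bind_rows(lapply(parts, `[[`, "us")),
       labels = cohort_tumor_table(cohort$spec))
}

#' Simulate a cohort and return its fused observation table
#'
#' Streams tumor by tumor (raw images are discarded once their features are
#' extracted), then randomly pairs the modality rows within each tumor.
#'
#' @param spec A [cohort_spec()].
#' @param params A [class_params()] table.
#' @param cfg A [glcm_config()].
#' @return The fused observation tibble (see [pair_modalities()]).
#' @export
simulate_fused <- function(spec = cohort_spec(),
                           params = class_params("well-separated"),
                           cfg = glcm_config()) {
  tumors <- cohort_tumor_table(spec)
  parts <- withr::with_seed(spec$seed, {
    lapply(seq_len(nrow(tumors)), function(k) {
      p <- params[params$label == tumors$label[k], ]
      tum <- c(list(tumor_id = tumors$tumor_id[k], label = tumors$label[k]),
               generate_tumor(p, spec$observations_per_tumor))
      extract_tumor_features(tum, cfg)
    })
  })
  feats <- list(drs = dplyr::bind_rows(lapply(parts, `[[`, "drs")),
                oct = dplyr::bind_rows(lapply(parts, `[[`, "oct")),
                us = dplyr::bind_rows(lapply(parts, `[[`, "us")))
  pair_modalities(feats$drs, feats$oct, feats$us, tumors,
                  seed = spec$seed + 1L)
}
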