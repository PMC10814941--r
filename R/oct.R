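#' OCT B-scans, regions of interest and the texture feature vector
#'
#' A B-scan is an 8-bit grayscale image stored as an integer matrix (rows =
#' depth, columns = lateral position) with pixel-pitch metadata. Texture is
#' summarised on a rectangular region of interest (ROI) by 4 first-order
#' statistics, Shannon entropy of the raw scan, and 5 Haralick features on
#' each of 12 gray-level co-occurrence matrices (4 angles x 3 interpixel
#' distances) - 65 values per ROI. Zero-intensity pixels are background and
#' are excluded throughout.
#'
#' @name oct
NULL

#' Construct a B-scan
#'
#' @param pixels Integer matrix of intensities in \[0, 255\].
#' @param axial_pitch_um,lateral_pitch_um Pixel pitch in micrometers (> 0).
#' @return An object of class `bscan` (an integer matrix with pitch
#'   attributes).
#' @export
bscan <- function(pixels, axial_pitch_um = 5.34, lateral_pitch_um = 7.32) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L) {
    rlang::abort("B-scan needs at least 2 rows and 2 columns",
                 class = "dermofuse_invalid_bscan")
  }
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L) {
    rlang::abort("B-scan intensities must be integers in [0, 255]",
                 class = "dermofuse_invalid_bscan")
  }
  if (axial_pitch_um <= 0 || lateral_pitch_um <= 0) {
    rlang::abort("pixel pitch must be positive",
                 class = "dermofuse_invalid_bscan")
  }
  structure(pixels, axial_pitch_um = axial_pitch_um,
            lateral_pitch_um = lateral_pitch_um, class = c("bscan", "matrix"))
}

#' Rectangular region of interest
#'
#' Offsets are 1-based row/column indices of the top-left pixel.
#'
#' @param row,col Top-left pixel of the region.
#' @param height,width Extent in pixels.
#' @return A `texture_roi` object.
#' @export
texture_roi <- function(row, col, height, width) {
  if (any(c(row, col) < 1L) || any(c(height, width) < 1L)) {
    rlang::abort("ROI offsets must be >= 1 and extents >= 1",
                 class = "dermofuse_invalid_roi")
  }
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width)),
            class = "texture_roi")
}

roi_rows <- function(roi) seq.int(roi$row, roi$row + roi$height - 1L)
roi_cols <- function(roi) seq.int(roi$col, roi$col + roi$width - 1L)

crop_roi <- function(scan, roi) {
  if (roi$row + roi$height - 1L > nrow(scan) ||
      roi$col + roi$width - 1L > ncol(scan)) {
    rlang::abort("ROI extends outside the B-scan",
                 class = "dermofuse_invalid_roi")
  }
  unclass(scan)[roi_rows(roi), roi_cols(roi), drop = FALSE]
}

#' Check the minimum physical ROI extent
#'
#' Analysis windows must span at least 534 um in depth and 400 um laterally
#' at the scan's pixel pitch.
#'
#' @param scan A [bscan()].
#' @param roi A [texture_roi()].
#' @param min_depth_um,min_width_um Minimum physical extent.
#' @return `roi`, invisibly, or an error.
#' @export
validate_roi_extent <- function(scan, roi, min_depth_um = 534,
                                min_width_um = 400) {
  crop_roi(scan, roi) # bounds check
  depth <- roi$height * attr(scan, "axial_pitch_um")
  width <- roi$width * attr(scan, "lateral_pitch_um")
  if (depth < min_depth_um || width < min_width_um) {
    rlang::abort(sprintf(
      "ROI spans %.0f x %.0f um; need at least %g um deep and %g um wide",
      depth, width, min_depth_um, min_width_um),
      class = "dermofuse_invalid_roi")
  }
  invisible(roi)
}

#' Estimate the background noise threshold
#'
#' Mean plus (population) standard deviation of the pixel intensities in a
#' region selected below the tissue image.
#'
#' @param scan A [bscan()].
#' @param background_region A [texture_roi()] covering pure background.
#' @return The scalar threshold.
#' @export
background_threshold <- function(scan, background_region) {
  px <- as.numeric(crop_roi(scan, background_region))
  if (length(px) == 0L) {
    rlang::abort("empty background region", class = "dermofuse_invalid_roi")
  }
  mean(px) + sqrt(mean((px - mean(px))^2))
}

#' Threshold filter
#'
#' Pixels with intensity less than or equal to the threshold are set to 0;
#' brighter pixels are untouched.
#'
#' @param scan A [bscan()].
#' @param threshold Nonnegative scalar.
#' @return The filtered `bscan`.
#' @export
threshold_filter <- function(scan, threshold) {
  stopifnot(threshold >= 0)
  out <- unclass(scan)
  out[out <= threshold] <- 0L
  bscan(out, attr(scan, "axial_pitch_um"), attr(scan, "lateral_pitch_um"))
}

#' Speckle denoising: grayscale erosion then Gaussian smoothing
#'
#' A 3x3 square minimum filter followed by a 2-D Gaussian smoothing kernel
#' with sigma = 1.5 px (truncated at 4 sigma), applied to the thresholded
#' scan; the result is re-quantized to \[0, 255\] integers by rounding.
#'
#' @param scan A [bscan()] (normally after [threshold_filter()]).
#' @param erosion_size Width of the square structuring element (pixels).
#' @param sigma Gaussian standard deviation in pixels.
#' @return The denoised `bscan`.
#' @export
denoise_bscan <- function(scan, erosion_size = 3, sigma = 1.5) {
  x <- unclass(scan) / 255
  x <- EBImage::erode(x, EBImage::makeBrush(erosion_size, shape = "box"))
  x <- EBImage::gblur(x, sigma = sigma, radius = 2L * ceiling(4 * sigma) + 1L)
  out <- pmin(pmax(round(x * 255), 0), 255)
  bscan(out, attr(scan, "axial_pitch_um"), attr(scan, "lateral_pitch_um"))
}

#' First-order statistics of an ROI
#'
#' Population moments of the gray-level distribution over the nonzero pixels
#' of the ROI: mean, standard deviation, skewness and (non-excess, Pearson)
#' kurtosis. A zero-variance ROI reports skewness and kurtosis as 0 with a
#' warning.
#'
#' @param scan A [bscan()].
#' @param roi A [texture_roi()].
#' @return A tibble with columns `fos_mean`, `fos_std`, `fos_skewness`,
#'   `fos_kurtosis`.
#' @export
first_order_stats <- function(scan, roi) {
  px <- as.numeric(crop_roi(scan, roi))
  px <- px[px > 0]
  if (length(px) < 2L) {
    rlang::abort("ROI has fewer than 2 nonzero pixels",
                 class = "dermofuse_degenerate_roi")
  }
  m <- mean(px)
  v <- mean((px - m)^2)
  if (v == 0) {
    rlang::warn("zero-variance ROI: skewness and kurtosis reported as 0")
    return(tibble::tibble(fos_mean = m, fos_std = 0,
                          fos_skewness = 0, fos_kurtosis = 0))
  }
  s <- sqrt(v)
  tibble::tibble(
    fos_mean = m,
    fos_std = s,
    fos_skewness = mean((px - m)^3) / s^3,
    fos_kurtosis = mean((px - m)^4) / v^2)
}

#' Shannon entropy of an ROI (bits)
#'
#' Computed on the raw (pre-denoising) B-scan from the 256-bin gray-level
#' histogram of the ROI, excluding zero (background) pixels; empty bins
#' contribute nothing.
#'
#' @inheritParams first_order_stats
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(scan, roi) {
  px <- as.integer(crop_roi(scan, roi))
  px <- px[px > 0]
  if (length(px) == 0L) {
    rlang::abort("ROI has no nonzero pixels", class = "dermofuse_degenerate_roi")
  }
  q <- tabulate(px, nbins = 255L)
  q <- q[q > 0] / length(px)
  -sum(q * log2(q))
}

#' GLCM configuration
#'
#' @param angles_deg Offset directions in degrees (image convention: rows
#'   increase downward; 0 = horizontal, 45 = up-right, 90 = vertical,
#'   135 = up-left).
#' @param distances_px Interpixel distances.
#' @param levels Number of gray levels (256 keeps the raw 8-bit range; lower
#'   values down-quantize).
#' @param homogeneity Kernel for the homogeneity sum: `"squared"` is the
#'   inverse difference moment 1/(1+(i-j)^2); `"abs"` uses 1/(1+|i-j|).
#' @param log_base Base of the entropy logarithms (2 = bits).
#' @return A `glcm_config` list.
#' @export
glcm_config <- function(angles_deg = c(0, 45, 90, 135),
                        distances_px = c(1, 5, 9),
                        levels = 256L,
                        homogeneity = c("squared", "abs"),
                        log_base = 2) {
  structure(list(angles_deg = angles_deg, distances_px = distances_px,
                 levels = as.integer(levels),
                 homogeneity = match.arg(homogeneity), log_base = log_base),
            class = "glcm_config")
}

glcm_offset <- function(angle_deg, distance_px) {
  d <- as.integer(distance_px)
  switch(as.character(angle_deg),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         rlang::abort("angle must be one of 0, 45, 90, 135",
                      class = "dermofuse_invalid_glcm"))
}

#' Gray-level co-occurrence matrix of an ROI
#'
#' Counts ordered pairs (pixel, pixel + offset) inside the ROI where both
#' pixels are nonzero, adds the transpose (symmetrization) and normalizes to
#' sum 1. Entry `p[i, j]` is the probability of gray levels (i-1, j-1) (or
#' their quantized bins) co-occurring at the given offset.
#'
#' @inheritParams first_order_stats
#' @param angle_deg,distance_px Offset direction and length (see
#'   [glcm_config()] for the convention).
#' @param levels Number of gray levels.
#' @return A `glcm` matrix (levels x levels) with attributes `angle_deg` and
#'   `distance_px`.
#' @export
glcm <- function(scan, roi, angle_deg, distance_px, levels = 256L) {
  a <- crop_roi(scan, roi)
  off <- glcm_offset(angle_deg, distance_px)
  if (abs(off[1]) >= nrow(a) || abs(off[2]) >= ncol(a)) {
    rlang::abort(sprintf("no valid pixel pairs for offset (%d, %d)",
                         off[1], off[2]),
                 class = "dermofuse_invalid_glcm")
  }
  sp <- glcm_sparse(a, angle_deg, distance_px, levels)
  levels <- as.integer(levels)
  m <- matrix(0, levels, levels)
  m[sp$gj * levels + sp$gi + 1L] <- sp$pv
  structure(m, angle_deg = angle_deg, distance_px = distance_px,
            class = c("glcm", "matrix"))
}

#' Haralick features of a co-occurrence matrix
#'
#' energy = sum p^2; contrast = sum (i-j)^2 p; correlation =
#' sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j) (defined as 1 when the
#' matrix is concentrated on a single gray level); entropy = -sum p log p
#' (zero entries skipped); homogeneity = sum p / (1 + (i-j)^2).
#'
#' @param p A normalized [glcm()] matrix.
#' @param homogeneity,log_base See [glcm_config()].
#' @return A one-row tibble with columns `energy`, `contrast`, `correlation`,
#'   `entropy`, `homogeneity`.
#' @export
haralick_features <- function(p, homogeneity = "squared", log_base = 2) {
  p <- unclass(p)
  if (abs(sum(p) - 1) > 1e-6) {
    rlang::abort("GLCM must be normalized to sum 1",
                 class = "dermofuse_invalid_glcm")
  }
  n <- nrow(p)
  # the matrix is sparse (at most one entry per pixel pair); every sum runs
  # over the nonzero entries only
  idx <- which(p > 0)
  pv <- p[idx]
  gi <- (idx - 1L) %% n            # gray level of the row index (0-based)
  gj <- (idx - 1L) %/% n
  haralick_from_sparse(gi, gj, pv, homogeneity, log_base)
}

haralick_from_sparse <- function(gi, gj, pv, homogeneity = "squared",
                                 log_base = 2) {
  mu_i <- sum(gi * pv)
  mu_j <- sum(gj * pv)
  var_i <- sum((gi - mu_i)^2 * pv)
  var_j <- sum((gj - mu_j)^2 * pv)
  cov_ij <- sum((gi - mu_i) * (gj - mu_j) * pv)
  corr <- if (var_i <= 0 || var_j <= 0) 1 else cov_ij / sqrt(var_i * var_j)
  dif2 <- (gi - gj)^2
  hom_kernel <- if (identical(homogeneity, "abs")) 1 / (1 + abs(gi - gj)) else
    1 / (1 + dif2)
  tibble::tibble(
    energy = sum(pv^2),
    contrast = sum(dif2 * pv),
    correlation = corr,
    entropy = -sum(pv * log(pv, base = log_base)),
    homogeneity = sum(hom_kernel * pv))
}

# sparse co-occurrence triplets for the extraction hot path: same counting,
# symmetrization and normalization as glcm(), without materializing the
# dense levels x levels matrix
glcm_sparse <- function(a, angle_deg, distance_px, levels = 256L) {
  off <- glcm_offset(angle_deg, distance_px)
  nr <- nrow(a); nc <- ncol(a)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  p1 <- a[r1, c1, drop = FALSE]
  p2 <- a[r1 + off[1], c1 + off[2], drop = FALSE]
  keep <- p1 > 0L & p2 > 0L
  if (!any(keep)) {
    rlang::abort(sprintf("no nonzero pixel pairs for offset (%d, %d)",
                         off[1], off[2]),
                 class = "dermofuse_invalid_glcm")
  }
  levels <- as.integer(levels)
  q1 <- pmin(as.integer(p1[keep] * (levels / 256)) + 1L, levels)
  q2 <- pmin(as.integer(p2[keep] * (levels / 256)) + 1L, levels)
  # count (q1, q2) and its transpose together (symmetrization)
  counts <- tabulate(c((q2 - 1L) * levels + q1, (q1 - 1L) * levels + q2),
                     nbins = levels * levels)
  idx <- which(counts > 0L)
  pv <- counts[idx] / sum(counts[idx])
  list(gi = (idx - 1L) %% levels, gj = (idx - 1L) %/% levels, pv = pv)
}

#' Names of the 65 OCT texture features
#'
#' 4 first-order statistics, the raw-scan Shannon entropy, and 5 Haralick
#' features for each of the 12 (angle, distance) co-occurrence
#' configurations, named `<feature>_a<angle>_d<distance>`.
#'
#' @param cfg A [glcm_config()].
#' @return Character vector of feature names, in emission order.
#' @export
oct_feature_names <- function(cfg = glcm_config()) {
  haralick <- c("energy", "contrast", "correlation", "entropy", "homogeneity")
  grid <- expand.grid(distance = cfg$distances_px, angle = cfg$angles_deg,
                      feature = haralick, stringsAsFactors = FALSE)
  c("fos_mean", "fos_std", "fos_skewness", "fos_kurtosis", "shannon_entropy",
    sprintf("%s_a%d_d%d", grid$feature, grid$angle, grid$distance))
}

#' Extract the full 65-value OCT texture feature vector
#'
#' Shannon entropy is computed from the raw scan; the scan is then threshold
#' filtered (threshold from the background region), denoised (erosion +
#' Gaussian), and the first-order statistics and the 12 x 5 Haralick features
#' are computed from the processed scan.
#'
#' @param scan A [bscan()].
#' @param roi Analysis [texture_roi()] (checked against the physical minimum
#'   extent).
#' @param background Background [texture_roi()] below the tissue.
#' @param cfg A [glcm_config()].
#' @return A one-row tibble with the 65 named feature columns.
#' @export
oct_features <- function(scan, roi, background, cfg = glcm_config()) {
  validate_roi_extent(scan, roi)
  ent <- shannon_entropy(scan, roi)
  thr <- background_threshold(scan, background)
  den <- denoise_bscan(threshold_filter(scan, thr))
  fos <- first_order_stats(den, roi)
  sub <- crop_roi(den, roi)
  har <- purrr::map(cfg$angles_deg, function(a) {
    purrr::map(cfg$distances_px, function(d) {
      sp <- glcm_sparse(sub, a, d, cfg$levels)
      h <- haralick_from_sparse(sp$gi, sp$gj, sp$pv, cfg$homogeneity,
                                cfg$log_base)
      names(h) <- sprintf("%s_a%d_d%d", names(h), a, d)
      h
    })
  })
  row <- dplyr::bind_cols(fos, tibble::tibble(shannon_entropy = ent),
                          purrr::flatten(har))
  row[, oct_feature_names(cfg)]
}
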