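#' Diffuse reflectance spectroscopy indices
#'
#' A diffuse reflectance (DR) spectrum is a tibble with two columns,
#' `wavelength_nm` (strictly increasing) and `reflectance` (the ratio of the
#' intensity reflected by the skin to that reflected by a near-100% reference;
#' strictly positive, nominally in (0, 1.5]). All chromophore indices are
#' computed from the effective optical density OD(lambda) = -log10 R(lambda)
#' at landmark wavelengths, which requires spectral coverage of at least
#' [500, 800] nm.
#'
#' @name drs
NULL

# landmark wavelengths (nm) used by the index formulas
.DRS_LANDMARKS <- c(500, 510, 529, 545, 560, 570, 575, 610, 620, 650, 700, 800)

#' Validate a reflectance spectrum table
#'
#' @param spectrum A data frame with columns `wavelength_nm` and `reflectance`.
#' @param require_coverage If `TRUE`, require the wavelength range to contain
#'   `[500, 800]` nm (needed by every landmark-based index).
#' @return The spectrum as a tibble, invisibly validated.
#' @export
validate_spectrum <- function(spectrum, require_coverage = TRUE) {
  spectrum <- tibble::as_tibble(spectrum)
  if (!all(c("wavelength_nm", "reflectance") %in% names(spectrum))) {
    rlang::abort("spectrum must have columns 'wavelength_nm' and 'reflectance'",
                 class = "dermofuse_invalid_spectrum")
  }
  wl <- spectrum$wavelength_nm
  r  <- spectrum$reflectance
  if (length(wl) < 2L || any(diff(wl) <= 0)) {
    rlang::abort("wavelengths must be strictly increasing, length >= 2",
                 class = "dermofuse_invalid_spectrum")
  }
  if (any(!is.finite(r)) || any(r <= 0)) {
    rlang::abort("reflectance must be finite and strictly positive",
                 class = "dermofuse_invalid_spectrum")
  }
  if (require_coverage && (min(wl) > 500 || max(wl) < 800)) {
    rlang::abort("spectrum must cover [500, 800] nm",
                 class = "dermofuse_invalid_spectrum")
  }
  spectrum
}

#' Convert a reflectance spectrum to optical density
#'
#' OD(lambda) = -log10 R(lambda), pointwise on the spectrum's own grid.
#'
#' @param spectrum A spectrum table (`wavelength_nm`, `reflectance`).
#' @return A tibble with columns `wavelength_nm` and `od`.
#' @export
#' @examples
#' sp <- tibble::tibble(wavelength_nm = 450:950, reflectance = 0.1)
#' optical_density(sp)$od[1] # 1
optical_density <- function(spectrum) {
  spectrum <- validate_spectrum(spectrum, require_coverage = FALSE)
  tibble::tibble(wavelength_nm = spectrum$wavelength_nm,
                 od = -log10(spectrum$reflectance))
}

#' Sample an optical density spectrum at a wavelength
#'
#' Linear interpolation between the two bracketing grid points; exact value
#' when the query sits on the grid. Spectrometer grids rarely hit the landmark
#' wavelengths exactly and linear interpolation is unbiased at ~1 nm pitch.
#'
#' @param od A tibble with columns `wavelength_nm` and `od`.
#' @param wavelength_nm Query wavelength(s) in nm, inside the grid range.
#' @return Interpolated OD value(s).
#' @export
od_at <- function(od, wavelength_nm) {
  wl <- od$wavelength_nm
  if (any(wavelength_nm < min(wl) | wavelength_nm > max(wl))) {
    rlang::abort(
      sprintf("wavelength outside spectrum range [%g, %g] nm", min(wl), max(wl)),
      class = "dermofuse_range_error")
  }
  stats::approx(wl, od$od, xout = wavelength_nm, method = "linear",
                ties = "ordered")$y
}

# reflectance sampled the same way (used by the malignancy coefficient)
reflectance_at <- function(spectrum, wavelength_nm) {
  wl <- spectrum$wavelength_nm
  if (any(wavelength_nm < min(wl) | wavelength_nm > max(wl))) {
    rlang::abort("wavelength outside spectrum range",
                 class = "dermofuse_range_error")
  }
  stats::approx(wl, spectrum$reflectance, xout = wavelength_nm,
                method = "linear", ties = "ordered")$y
}

#' Melanin pigmentation index
#'
#' M = 100 (OD620 - OD700). Melanin absorption decays smoothly with
#' wavelength, so the 620/700 nm optical density drop scales with melanin
#' content.
#'
#' @param od Optical density tibble (see [optical_density()]).
#' @return The melanin index (dimensionless).
#' @export
melanin_index <- function(od) {
  v <- od_at(od, c(620, 700))
  100 * (v[1] - v[2])
}

#' Erythema index
#'
#' E = 100 \[OD560 + 1.5 (OD545 + OD575) - 2 (OD510 + OD610)\]: the classical
#' Dawson contrast of the oxyhemoglobin double peak (545/575 nm) against the
#' flanking baseline at 510 and 610 nm. The coefficients sum to zero, so any
#' spectrally flat (or affine-in-wavelength) OD contributes nothing.
#'
#' @inheritParams melanin_index
#' @return The erythema index (dimensionless).
#' @export
erythema_index <- function(od) {
  v <- od_at(od, c(510, 545, 560, 575, 610))
  100 * (v[3] + 1.5 * (v[2] + v[4]) - 2 * (v[1] + v[5]))
}

#' Hemoglobin content index
#'
#' H = (OD545 - OD529)/16 - (OD570 - OD545)/25, a two-sided finite-difference
#' estimate of the curvature of the optical density around the 545 nm
#' hemoglobin peak; affine OD trends cancel exactly.
#'
#' @inheritParams melanin_index
#' @return The hemoglobin index (dimensionless).
#' @export
hemoglobin_index <- function(od) {
  v <- od_at(od, c(529, 545, 570))
  (v[2] - v[1]) / 16 - (v[3] - v[2]) / 25
}

#' Spectral slope (linearity) of the reflectance in 650-800 nm
#'
#' Ordinary least-squares line fit of reflectance against wavelength
#' restricted to the 650-800 nm window, where healthy skin reflectance is
#' close to linear. `linearity` is the fitted slope (per nm);
#' `error_linearity` is the root-mean-square of the fit residuals
#' (dimensionless, reflectance units), quantifying deviation from the linear
#' approximation.
#'
#' @param spectrum A reflectance spectrum table.
#' @return A list with elements `linearity` and `error_linearity`.
#' @export
reflectance_linearity <- function(spectrum) {
  spectrum <- validate_spectrum(spectrum, require_coverage = FALSE)
  keep <- spectrum$wavelength_nm >= 650 & spectrum$wavelength_nm <= 800
  if (sum(keep) < 3L) {
    rlang::abort("need >= 3 samples in [650, 800] nm for the linearity fit",
                 class = "dermofuse_insufficient_data")
  }
  x <- spectrum$wavelength_nm[keep]
  y <- spectrum$reflectance[keep]
  fit <- stats::lm.fit(cbind(1, x), y)
  list(linearity = unname(fit$coefficients[2]),
       error_linearity = sqrt(mean(fit$residuals^2)))
}

#' Malignancy coefficient Rt
#'
#' Rt = (R_healthy(500) R_lesion(700)) / (R_healthy(700) R_lesion(500)): a
#' two-wavelength contrast of the lesion spectrum against healthy skin.
#' Identical spectra give exactly 1, and swapping the roles inverts the value.
#'
#' @param lesion,healthy Reflectance spectrum tables.
#' @return The malignancy coefficient (dimensionless, > 0).
#' @export
malignancy_coefficient <- function(lesion, healthy) {
  lesion  <- validate_spectrum(lesion,  require_coverage = FALSE)
  healthy <- validate_spectrum(healthy, require_coverage = FALSE)
  rh <- reflectance_at(healthy, c(500, 700))
  rn <- reflectance_at(lesion,  c(500, 700))
  (rh[1] * rn[2]) / (rh[2] * rn[1])
}

# all five per-spectrum coefficients, unnormalized
drs_raw_row <- function(spectrum) {
  spectrum <- validate_spectrum(spectrum)
  od <- optical_density(spectrum)
  lin <- reflectance_linearity(spectrum)
  tibble::tibble(
    M = melanin_index(od),
    E = erythema_index(od),
    H = hemoglobin_index(od),
    Linearity = lin$linearity,
    Error_linearity = lin$error_linearity)
}

# pointwise mean spectrum over a list of spectra, interpolated onto the grid
# of the first one
mean_spectrum <- function(spectra) {
  grid <- spectra[[1]]$wavelength_nm
  vals <- vapply(spectra, function(s) {
    stats::approx(s$wavelength_nm, s$reflectance, xout = grid, rule = 2,
                  ties = "ordered")$y
  }, numeric(length(grid)))
  tibble::tibble(wavelength_nm = grid, reflectance = rowMeans(vals))
}

#' Extract normalized DRS features for one tumor
#'
#' Computes the melanin (M), erythema (E), hemoglobin (H), spectral-slope
#' (Linearity, Error_linearity) and malignancy (Rt) coefficients for each
#' lesion spectrum. To remove the volunteer's individual skin spectrum, each
#' of M/E/H/Linearity/Error_linearity is divided by the mean of the same
#' coefficient over the healthy-skin spectra; Rt is computed against the
#' pointwise mean healthy spectrum and is not re-normalized (it is already a
#' lesion/healthy contrast).
#'
#' @param lesion_spectra,healthy_spectra Either a list of spectrum tibbles or
#'   a single long tibble with columns `obs_idx`, `wavelength_nm`,
#'   `reflectance`.
#' @param guard_eps Healthy-mean magnitudes at or below this threshold abort
#'   with the offending coefficient named (no silent clipping).
#' @return A tibble with one row per lesion spectrum: `obs_idx`, `M`, `E`,
#'   `H`, `Linearity`, `Error_linearity`, `Rt`.
#' @export
drs_features <- function(lesion_spectra, healthy_spectra, guard_eps = 1e-12) {
  lesion_spectra  <- as_spectrum_list(lesion_spectra)
  healthy_spectra <- as_spectrum_list(healthy_spectra)
  if (length(lesion_spectra) < 1L || length(healthy_spectra) < 1L) {
    rlang::abort("need at least one spectrum per site",
                 class = "dermofuse_invalid_spectrum")
  }
  lesion_raw  <- dplyr::bind_rows(lapply(lesion_spectra, drs_raw_row))
  healthy_raw <- dplyr::bind_rows(lapply(healthy_spectra, drs_raw_row))
  healthy_mean <- colMeans(healthy_raw)
  bad <- names(healthy_mean)[abs(healthy_mean) <= guard_eps]
  if (length(bad) > 0L) {
    rlang::abort(
      paste0("healthy-skin mean is zero (within guard_eps) for coefficient(s): ",
             paste(bad, collapse = ", ")),
      class = "dermofuse_division_guard")
  }
  healthy_ref <- mean_spectrum(healthy_spectra)
  normalized <- sweep(as.matrix(lesion_raw), 2, healthy_mean, "/")
  out <- tibble::as_tibble(normalized)
  out$Rt <- vapply(lesion_spectra, malignancy_coefficient, numeric(1),
                   healthy = healthy_ref)
  dplyr::bind_cols(tibble::tibble(obs_idx = seq_along(lesion_spectra)), out)
}

# accept a list of spectra or a long tibble keyed by obs_idx
as_spectrum_list <- function(x) {
  if (is.data.frame(x)) {
    if ("obs_idx" %in% names(x)) {
      x <- dplyr::arrange(x, .data$obs_idx, .data$wavelength_nm)
      return(unname(split(x[c("wavelength_nm", "reflectance")], x$obs_idx)))
    }
    return(list(tibble::as_tibble(x)))
  }
  lapply(x, tibble::as_tibble)
}
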