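#' Class-dependent generator parameters
#'
#' Each diagnosis class gets a phenomenological parameter set driving every
#' modality of the synthetic cohort: the melanin OD ramp (`melanin_slope`,
#' recovered downstream as M ~ 100 x melanin_slope), the oxyhemoglobin
#' double-dip depth at 545/575 nm (`hemoglobin_dip_depth`, driving E and H),
#' the near-infrared reflectance trend (`nir_slope`, per nm, driving
#' Linearity), the OCT texture field (`mean_intensity`,
#' `texture_correlation_length_px`, `texture_contrast`) and the lesion
#' geometry on ultrasound (`shape_eccentricity`, `boundary_roughness`,
#' `size_mm` as equivalent diameter). `noise_sd_drs` is additive reflectance
#' noise, `annotator_jitter` the relative radial disagreement between the
#' two simulated annotators and `tumor_jitter` the relative sd of the
#' per-tumor random effect on every class parameter.
#'
#' Two presets exist. `"well-separated"` places the six classes far apart on
#' several feature axes relative to all noise sources, honouring the ordinal
#' relations seen clinically: melanin highest for benign lesions and the
#' pigmented carcinoma form, erythema/hemoglobin highest for the nodular and
#' lowest for the superficial form, and circularity high for benign lesions
#' but low (rough, eccentric) for the superficial form. `"overlapping"`
#' shrinks the class separations towards their common mean and inflates
#' every noise source, so classes genuinely overlap.
#'
#' @param preset `"well-separated"` or `"overlapping"`.
#' @return Tibble of per-class generator parameters (class
#'   `class_params`).
#' @export
class_params <- function(preset = c("well-separated", "overlapping")) {
  preset <- match.arg(preset)
  base <- tibble::tribble(
    ~label, ~melanin_slope, ~hemoglobin_dip_depth, ~nir_slope,
    ~mean_intensity, ~texture_correlation_length_px, ~texture_contrast,
    ~shape_eccentricity, ~boundary_roughness, ~size_mm,
    "infiltrative_ulcerative_bcc", 0.060, 0.10, -1.0e-4, 150, 5.0, 35, 0.55, 0.15, 6.0,
    "pigmented_bcc",               0.220, 0.06, -4.0e-4,  90, 2.0, 25, 0.45, 0.10, 5.0,
    "superficial_bcc",             0.040, 0.03,  2.0e-4, 120, 1.5, 45, 0.85, 0.25, 8.0,
    "morpheaform_bcc",             0.100, 0.14,  0.5e-4, 170, 8.0, 20, 0.65, 0.12, 4.0,
    "nodular_bcc",                 0.080, 0.22, -2.0e-4, 140, 3.5, 55, 0.35, 0.05, 7.0,
    "benign",                      0.250, 0.08,  1.0e-4, 110, 6.0, 30, 0.10, 0.03, 5.5)
  if (preset == "well-separated") {
    base$noise_sd_drs <- 0.004
    base$annotator_jitter <- 0.02
    base$tumor_jitter <- 0.02
  } else {
    # pull every class parameter 65% of the way to the across-class mean and
    # inflate the noise sources
    num <- setdiff(names(base), "label")
    mid <- colMeans(base[num])
    for (f in num) base[[f]] <- mid[[f]] + (base[[f]] - mid[[f]]) * 0.35
    base$noise_sd_drs <- 0.02
    base$annotator_jitter <- 0.08
    base$tumor_jitter <- 0.25
  }
  structure(base, preset = preset, class = c("class_params", class(base)))
}

#' Cohort layout specification
#'
#' Defaults mirror the study inventory: 37 tumors split 2 / 2 / 15 / 3 / 5
#' / 10 over the six classes, 10 observations per tumor per modality (10
#' lesion + 10 healthy spectra, 10 OCT B-scans, 10 ultrasound mask pairs).
#'
#' @param tumors_per_class Named integer vector over [diagnosis_levels()].
#' @param observations_per_tumor Rows per modality per tumor.
#' @param seed Integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(tumors_per_class = c(
                          infiltrative_ulcerative_bcc = 2L,
                          pigmented_bcc = 2L,
                          superficial_bcc = 15L,
                          morpheaform_bcc = 3L,
                          nodular_bcc = 5L,
                          benign = 10L),
                        observations_per_tumor = 10L,
                        seed = 1L) {
  stopifnot(all(names(tumors_per_class) %in% diagnosis_levels()),
            all(tumors_per_class >= 1L), observations_per_tumor >= 1L)
  structure(list(tumors_per_class = tumors_per_class,
                 observations_per_tumor = as.integer(observations_per_tumor),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}
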