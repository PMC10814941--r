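#' On-disk cohort layout and manifest-driven extraction
#'
#' The pipeline's file interface mirrors what a clinical export would look
#' like: one CSV per spectrum (`wavelength_nm,reflectance`) with a manifest
#' mapping tumor/site/path; 8-bit grayscale PNG B-scans with an annotation
#' CSV carrying ROI, background-region and pixel-pitch columns; two binary
#' PNG masks per ultrasound image with a manifest carrying pixel spacing;
#' and a `labels.csv` (`tumor_id,label`).
#'
#' @name cohort_io
NULL

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

read_csv_plain <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly. Writes `drs/`, `oct/`, `us/` subdirectories,
#'   the three manifests (`drs_manifest.csv`, `oct_manifest.csv`,
#'   `us_manifest.csv`) and `labels.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  for (d in file.path(dir, c("drs", "oct", "us"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  drs_rows <- list(); oct_rows <- list(); us_rows <- list()
  for (tum in cohort$tumors) {
    tid <- tum$tumor_id
    for (site in c("lesion", "healthy")) {
      spectra <- tum[[paste0("spectra_", site)]]
      for (i in seq_along(spectra)) {
        rel <- sprintf("drs/%s_%s_%02d.csv", tid, site, i)
        write_csv_plain(spectra[[i]], file.path(dir, rel))
        drs_rows[[length(drs_rows) + 1L]] <- tibble::tibble(
          tumor_id = tid, site = site, obs_idx = i, path = rel)
      }
    }
    for (i in seq_along(tum$oct)) {
      o <- tum$oct[[i]]
      rel <- sprintf("oct/%s_%02d.png", tid, i)
      png::writePNG(unclass(o$scan) / 255, file.path(dir, rel))
      oct_rows[[length(oct_rows) + 1L]] <- tibble::tibble(
        tumor_id = tid, obs_idx = i, path = rel,
        roi_row = o$roi$row, roi_col = o$roi$col,
        roi_h = o$roi$height, roi_w = o$roi$width,
        bg_row = o$background$row, bg_col = o$background$col,
        bg_h = o$background$height, bg_w = o$background$width,
        axial_um = attr(o$scan, "axial_pitch_um"),
        lateral_um = attr(o$scan, "lateral_pitch_um"))
    }
    for (i in seq_along(tum$us)) {
      m <- tum$us[[i]]
      rel_a <- sprintf("us/%s_%02d_a.png", tid, i)
      rel_b <- sprintf("us/%s_%02d_b.png", tid, i)
      png::writePNG(unclass(m$mask_a) * 1, file.path(dir, rel_a))
      png::writePNG(unclass(m$mask_b) * 1, file.path(dir, rel_b))
      sp <- attr(m$mask_a, "spacing_mm")
      us_rows[[length(us_rows) + 1L]] <- tibble::tibble(
        tumor_id = tid, obs_idx = i,
        path_annotator1 = rel_a, path_annotator2 = rel_b,
        row_spacing_mm = sp[1], col_spacing_mm = sp[2])
    }
  }
  write_csv_plain(dplyr::bind_rows(drs_rows), file.path(dir, "drs_manifest.csv"))
  write_csv_plain(dplyr::bind_rows(oct_rows), file.path(dir, "oct_manifest.csv"))
  write_csv_plain(dplyr::bind_rows(us_rows), file.path(dir, "us_manifest.csv"))
  write_csv_plain(cohort_tumor_table(cohort$spec), file.path(dir, "labels.csv"))
  invisible(dir)
}

read_png_gray <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  round(img * 255)
}

#' Extract DRS features from an on-disk manifest
#'
#' @param manifest_path Path to `drs_manifest.csv` (columns `tumor_id`,
#'   `site`, `obs_idx`, `path`, paths relative to the manifest's directory).
#' @return Tibble `tumor_id`, `obs_idx` + the six DRS features.
#' @export
drs_features_from_manifest <- function(manifest_path) {
  root <- dirname(manifest_path)
  man <- read_csv_plain(manifest_path)
  out <- lapply(split(man, man$tumor_id), function(mt) {
    load_site <- function(site) {
      rows <- mt[mt$site == site, ]
      rows <- rows[order(rows$obs_idx), ]
      lapply(rows$path, function(p) read_csv_plain(file.path(root, p)))
    }
    feats <- drs_features(load_site("lesion"), load_site("healthy"))
    dplyr::bind_cols(tibble::tibble(tumor_id = mt$tumor_id[1]), feats)
  })
  dplyr::bind_rows(out)
}

#' Extract OCT texture features from an on-disk manifest
#'
#' @param manifest_path Path to `oct_manifest.csv`.
#' @param cfg A [glcm_config()].
#' @return Tibble `tumor_id`, `obs_idx` + the 65 OCT features.
#' @export
oct_features_from_manifest <- function(manifest_path, cfg = glcm_config()) {
  root <- dirname(manifest_path)
  man <- read_csv_plain(manifest_path)
  rows <- lapply(seq_len(nrow(man)), function(k) {
    m <- man[k, ]
    scan <- bscan(read_png_gray(file.path(root, m$path)),
                  m$axial_um, m$lateral_um)
    dplyr::bind_cols(
      tibble::tibble(tumor_id = m$tumor_id, obs_idx = m$obs_idx),
      oct_features(scan,
                   texture_roi(m$roi_row, m$roi_col, m$roi_h, m$roi_w),
                   texture_roi(m$bg_row, m$bg_col, m$bg_h, m$bg_w),
                   cfg))
  })
  dplyr::bind_rows(rows)
}

#' Extract ultrasound shape features from an on-disk manifest
#'
#' @param manifest_path Path to `us_manifest.csv`.
#' @return Tibble `tumor_id`, `obs_idx` + the 13 shape features.
#' @export
us_features_from_manifest <- function(manifest_path) {
  root <- dirname(manifest_path)
  man <- read_csv_plain(manifest_path)
  rows <- lapply(seq_len(nrow(man)), function(k) {
    m <- man[k, ]
    sp <- c(m$row_spacing_mm, m$col_spacing_mm)
    a <- roi_mask(read_png_gray(file.path(root, m$path_annotator1)) > 127, sp)
    b <- roi_mask(read_png_gray(file.path(root, m$path_annotator2)) > 127, sp)
    dplyr::bind_cols(
      tibble::tibble(tumor_id = m$tumor_id, obs_idx = m$obs_idx),
      shape_features(consensus_roi(a, b)))
  })
  dplyr::bind_rows(rows)
}

#' Write a fused table with its provenance sidecar
#'
#' @param fused A [pair_modalities()] result.
#' @param path Output CSV path; a JSON sidecar `<path>.json` records the
#'   pairing seed and scaling mode.
#' @param scaling Scaling mode string recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_fused <- function(fused, path, scaling = "per_fold") {
  write_csv_plain(fused, path)
  jsonlite::write_json(
    list(seed = attr(fused, "seed"), scaling = scaling,
         n_observations = nrow(fused)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
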