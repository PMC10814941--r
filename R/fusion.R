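#' Cross-modal fusion of per-tumor feature rows
#'
#' The three modalities are acquired at spatially inconsistent sites of the
#' same tumor, so rows cannot be co-registered; instead each observation of a
#' tumor is assembled by randomly pairing one DRS row, one OCT row and one
#' ultrasound row of that tumor, without reusing any source row.
#'
#' @name fusion
NULL

#' Diagnosis class levels
#'
#' The closed six-class label set: five clinical forms of basal cell
#' carcinoma plus benign neoplasms.
#'
#' @return Character vector of the six class labels.
#' @export
diagnosis_levels <- function() {
  c("infiltrative_ulcerative_bcc", "pigmented_bcc", "superficial_bcc",
    "morpheaform_bcc", "nodular_bcc", "benign")
}

#' Collapse the six classes to the binary bcc/benign view
#'
#' @param labels Factor or character vector of diagnosis labels.
#' @return Factor with levels `bcc`, `benign`.
#' @export
collapse_binary <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), diagnosis_levels())
  if (length(bad) > 0L) {
    rlang::abort(paste0("unknown diagnosis label(s): ", paste(bad, collapse = ", ")),
                 class = "dermofuse_invalid_label")
  }
  factor(ifelse(labels == "benign", "benign", "bcc"),
         levels = c("bcc", "benign"))
}

#' Randomly pair modality rows into fused observations
#'
#' For every tumor, draws an independent uniform random permutation of each
#' modality's rows and zips them, producing min(n_drs, n_oct, n_us)
#' observations; each source row is used at most once. Feature values are
#' permuted, never altered.
#'
#' @param drs,oct,us Feature tibbles with `tumor_id`, `obs_idx` and the
#'   modality's feature columns.
#' @param labels Tibble `tumor_id`, `label` (one row per tumor; labels must
#'   be in [diagnosis_levels()]).
#' @param seed Integer seed for the pairing permutations (recorded on the
#'   result).
#' @return A fused tibble with `tumor_id`, `label`, `obs_idx` and the 84
#'   feature columns; the source-row assignment is kept in the `pairing`
#'   attribute for audit.
#' @export
pair_modalities <- function(drs, oct, us, labels, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  mods <- list(drs = tibble::as_tibble(drs), oct = tibble::as_tibble(oct),
               us = tibble::as_tibble(us))
  for (m in names(mods)) {
    if (!all(c("tumor_id", "obs_idx") %in% names(mods[[m]]))) {
      rlang::abort(sprintf("%s table must have tumor_id and obs_idx columns", m),
                   class = "dermofuse_invalid_table")
    }
  }
  labels <- tibble::as_tibble(labels)
  tumors <- labels$tumor_id
  withr::with_seed(as.integer(seed), {
    fused <- lapply(tumors, function(tid) {
      parts <- lapply(stats::setNames(nm = names(mods)), function(m) {
        rows <- mods[[m]][mods[[m]]$tumor_id == tid, ]
        if (nrow(rows) == 0L) {
          rlang::abort(sprintf("tumor '%s' has no rows for modality '%s'",
                               tid, m),
                       class = "dermofuse_missing_modality")
        }
        rows
      })
      n <- min(vapply(parts, nrow, integer(1)))
      perm <- lapply(parts, function(p) sample.int(nrow(p))[seq_len(n)])
      feat <- purrr::map2(parts, perm, function(p, ix) {
        dplyr::select(p[ix, ], -"tumor_id", -"obs_idx")
      })
      audit <- tibble::tibble(
        tumor_id = tid, obs_idx = seq_len(n),
        drs_row = parts$drs$obs_idx[perm$drs],
        oct_row = parts$oct$obs_idx[perm$oct],
        us_row = parts$us$obs_idx[perm$us])
      list(rows = dplyr::bind_cols(
        tibble::tibble(tumor_id = tid,
                       label = labels$label[labels$tumor_id == tid][1],
                       obs_idx = seq_len(n)),
        feat$drs, feat$oct, feat$us),
        audit = audit)
    })
  })
  out <- dplyr::bind_rows(purrr::map(fused, "rows"))
  out$label <- factor(as.character(out$label), levels = diagnosis_levels())
  attr(out, "pairing") <- dplyr::bind_rows(purrr::map(fused, "audit"))
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Feature columns of a fused table
#'
#' @param fused A fused tibble.
#' @return Names of all columns except `tumor_id`, `label`, `obs_idx`.
#' @export
feature_columns <- function(fused) {
  setdiff(names(fused), c("tumor_id", "label", "obs_idx"))
}

#' Fit min-max scaling parameters on training rows
#'
#' @param train Data frame of training rows.
#' @param features Character vector of feature columns (default: all feature
#'   columns of a fused table).
#' @return A tibble `feature`, `min`, `max` (class `minmax_params`).
#' @export
fit_minmax <- function(train, features = feature_columns(train)) {
  if (nrow(train) < 2L) {
    rlang::abort("need >= 2 training rows to fit scaling",
                 class = "dermofuse_invalid_table")
  }
  out <- tibble::tibble(
    feature = features,
    min = vapply(train[features], min, numeric(1)),
    max = vapply(train[features], max, numeric(1)))
  class(out) <- c("minmax_params", class(out))
  out
}

#' Apply min-max scaling
#'
#' scaled = (x - min) / (max - min) per feature, using training-fold
#' parameters. Constant features map to 0; values outside the training range
#' extrapolate beyond \[0, 1\] (no clipping).
#'
#' @param rows Data frame to scale.
#' @param params A [fit_minmax()] result.
#' @return `rows` with the scaled feature columns.
#' @export
apply_minmax <- function(rows, params) {
  rows <- tibble::as_tibble(rows)
  for (k in seq_len(nrow(params))) {
    f <- params$feature[k]
    rng <- params$max[k] - params$min[k]
    rows[[f]] <- if (rng == 0) rep(0, nrow(rows)) else
      (rows[[f]] - params$min[k]) / rng
  }
  rows
}

#' Inverse of min-max scaling (non-constant features)
#'
#' @inheritParams apply_minmax
#' @return `rows` with feature columns mapped back to the original scale.
#' @export
invert_minmax <- function(rows, params) {
  rows <- tibble::as_tibble(rows)
  for (k in seq_len(nrow(params))) {
    f <- params$feature[k]
    rng <- params$max[k] - params$min[k]
    if (rng != 0) rows[[f]] <- rows[[f]] * rng + params$min[k]
  }
  rows
}

#' Inverse-frequency class weights
#'
#' weight(c) is proportional to 1 / count(c), normalized so the mean weight
#' over observations is 1 (smaller classes get more weight, and the total
#' loss magnitude stays comparable across training folds).
#'
#' @param labels Factor or character vector of observation labels.
#' @return Tibble `label`, `count`, `weight` over the classes present.
#' @export
class_weights <- function(labels) {
  labels <- as.character(labels)
  counts <- table(labels)
  k <- length(counts)
  n <- length(labels)
  tibble::tibble(
    label = names(counts),
    count = as.integer(counts),
    weight = n / (k * as.numeric(counts)))
}
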