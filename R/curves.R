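#' Probability-threshold and ROC curves
#'
#' One-vs-rest per class: an observation is called positive for a class when
#' its predicted probability for that class reaches the threshold. Sweeping
#' the threshold over a fixed grid yields the false-positive and
#' false-negative proportions used to tune the operating point, and the ROC
#' pairs (FPR, TPR); at matching thresholds FNR = 1 - TPR.
#'
#' @name curves
NULL

oof_prob_matrix <- function(x) {
  pcols <- paste0("p_", diagnosis_levels())
  as.matrix(x$oof[pcols])
}

#' Threshold sweep of FPR / FNR / TPR per class
#'
#' @param x A `bcc_loocv` object, or a matrix of class probabilities with
#'   one column per class.
#' @param truth True labels (required when `x` is a matrix).
#' @param step Threshold grid step on \[0, 1\].
#' @return Tibble `class`, `threshold`, `fpr`, `fnr`, `tpr`.
#' @export
threshold_curves <- function(x, truth = NULL, step = 0.01) {
  if (inherits(x, "bcc_loocv")) {
    probs <- oof_prob_matrix(x)
    colnames(probs) <- diagnosis_levels()
    truth <- x$oof$label
    step <- x$config$threshold_step
  } else {
    probs <- as.matrix(x)
    if (is.null(truth)) {
      rlang::abort("truth labels required", class = "dermofuse_invalid_table")
    }
  }
  truth <- as.character(truth)
  grid <- seq(0, 1, by = step)
  out <- purrr::map(colnames(probs), function(cl) {
    pos <- truth == cl
    n_pos <- sum(pos); n_neg <- sum(!pos)
    p <- probs[, cl]
    fpr <- vapply(grid, function(t) {
      if (n_neg == 0) 0 else sum(p[!pos] >= t) / n_neg
    }, numeric(1))
    fnr <- vapply(grid, function(t) {
      if (n_pos == 0) 0 else sum(p[pos] < t) / n_pos
    }, numeric(1))
    tibble::tibble(class = cl, threshold = grid, fpr = fpr, fnr = fnr,
                   tpr = 1 - fnr)
  })
  dplyr::bind_rows(out)
}

#' One-vs-rest ROC points per class
#'
#' The same threshold sweep as [threshold_curves()], reported as (FPR, TPR)
#' pairs.
#'
#' @inheritParams threshold_curves
#' @return Tibble `class`, `threshold`, `fpr`, `tpr`.
#' @export
roc_curves <- function(x, truth = NULL, step = 0.01) {
  tc <- threshold_curves(x, truth, step)
  tc[c("class", "threshold", "fpr", "tpr")]
}
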