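#' Confusion matrices and the Sens/Spec/Prec/F1/IoU metric suite
#'
#' Per class c of a K x K confusion matrix (rows = true class, columns =
#' predicted): tp is the diagonal entry, fn the rest of the row, fp the rest
#' of the column and tn everything else, giving
#' Sens = tp / (tp + fn), Spec = tn / (tn + fp), Prec = tp / (tp + fp),
#' F1 = 2 Prec Sens / (Prec + Sens) and IoU = tp / (tp + fn + fp). Macro
#' scores are unweighted class means, reported with the across-class
#' standard deviation.
#'
#' @name metrics
NULL

#' Build a confusion matrix from truth and predictions
#'
#' @param truth,predicted Factors (or vectors coercible to factors) on the
#'   same label set.
#' @param levels Class levels fixing row/column order.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted,
                             levels = union(unique(as.character(truth)),
                                            unique(as.character(predicted)))) {
  truth <- factor(as.character(truth), levels = levels)
  predicted <- factor(as.character(predicted), levels = levels)
  unclass(table(truth = truth, predicted = predicted))
}

#' Metric suite from a confusion matrix
#'
#' Undefined ratios (a class with no true or no predicted observations) are
#' reported as 0 and flagged in the `degenerate` column so macro means stay
#' computable.
#'
#' @param cm Square confusion matrix (rows = truth).
#' @return A `bcc_metrics` object: list with `per_class` (tibble of class,
#'   tp/fp/fn/tn, Sens, Spec, Prec, F1, IoU, degenerate) and `macro` (tibble
#'   of metric, mean, sd).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || sum(cm) == 0) {
    rlang::abort("confusion matrix must be square with positive total",
                 class = "dermofuse_invalid_table")
  }
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  total <- sum(cm)
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  per <- purrr::map(seq_len(nrow(cm)), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    sens <- safe(tp, tp + fn)
    spec <- safe(tn, tn + fp)
    prec <- safe(tp, tp + fp)
    f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
    tibble::tibble(class = classes[k], tp = tp, fp = fp, fn = fn, tn = tn,
                   Sens = sens, Spec = spec, Prec = prec, F1 = f1,
                   IoU = safe(tp, tp + fn + fp),
                   degenerate = (tp + fn == 0) || (tp + fp == 0))
  })
  per <- dplyr::bind_rows(per)
  macro <- tidyr::pivot_longer(per[c("Sens", "Spec", "Prec", "F1", "IoU")],
                               dplyr::everything(),
                               names_to = "metric", values_to = "value")
  macro <- dplyr::summarise(dplyr::group_by(macro, .data$metric),
                            mean = mean(.data$value),
                            sd = stats::sd(.data$value), .groups = "drop")
  macro <- macro[match(c("Sens", "Spec", "Prec", "F1", "IoU"), macro$metric), ]
  structure(list(per_class = per, macro = macro, confusion = cm),
            class = "bcc_metrics")
}

#' @export
print.bcc_metrics <- function(x, ...) {
  cat("Per-class metrics:\n")
  print(as.data.frame(x$per_class[c("class", "Sens", "Spec", "Prec", "F1", "IoU")]),
        digits = 3, row.names = FALSE)
  cat("Macro (mean +/- across-class sd):\n")
  for (k in seq_len(nrow(x$macro))) {
    cat(sprintf("  %-5s %.1f +/- %.1f %%\n", x$macro$metric[k],
                100 * x$macro$mean[k], 100 * x$macro$sd[k]))
  }
  invisible(x)
}

#' Metric suite of a LOOCV run
#'
#' @param x A `bcc_loocv` object.
#' @return A `bcc_metrics` object over the six diagnosis classes.
#' @export
loocv_metrics <- function(x) {
  stopifnot(inherits(x, "bcc_loocv"))
  metrics_from_confusion(
    confusion_matrix(x$oof$label, x$oof$predicted, diagnosis_levels()))
}

#' Binary (bcc vs benign) view of multiclass predictions
#'
#' Collapses the five carcinoma classes into one on the argmax predictions
#' before rebuilding the confusion matrix, mirroring a screening decision
#' that ignores the clinical form.
#'
#' @param x A `bcc_loocv` object, or a factor of true labels.
#' @param predicted When `x` is a label vector: the argmax predictions.
#' @return A `bcc_metrics` object over `bcc` and `benign`.
#' @export
binary_view <- function(x, predicted = NULL) {
  if (inherits(x, "bcc_loocv")) {
    truth <- x$oof$label
    predicted <- x$oof$predicted
  } else {
    truth <- x
    if (is.null(predicted)) {
      rlang::abort("predicted labels required", class = "dermofuse_invalid_table")
    }
  }
  metrics_from_confusion(confusion_matrix(
    collapse_binary(truth), collapse_binary(predicted),
    levels = c("bcc", "benign")))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-class metrics
#'
#' @param x A `bcc_metrics` object.
#' @param ... Unused.
#' @return The per-class metric tibble.
#' @method tidy bcc_metrics
#' @export
tidy.bcc_metrics <- function(x, ...) x$per_class

#' One-row macro summary of a metric suite
#'
#' @inheritParams tidy.bcc_metrics
#' @return One-row tibble: macro mean and across-class sd per metric.
#' @method glance bcc_metrics
#' @export
glance.bcc_metrics <- function(x, ...) {
  wide <- c(stats::setNames(x$macro$mean, paste0("macro_", x$macro$metric)),
            stats::setNames(x$macro$sd, paste0("sd_", x$macro$metric)))
  tibble::as_tibble(as.list(wide))
}

#' Tidy out-of-fold LOOCV predictions
#'
#' @param x A `bcc_loocv` object.
#' @param ... Unused.
#' @return The out-of-fold prediction tibble.
#' @method tidy bcc_loocv
#' @export
tidy.bcc_loocv <- function(x, ...) x$oof

#' One-row summary of a LOOCV run
#'
#' @inheritParams tidy.bcc_loocv
#' @return One-row tibble: folds, observations, argmax accuracy and macro
#'   metrics of the multiclass view.
#' @method glance bcc_loocv
#' @export
glance.bcc_loocv <- function(x, ...) {
  m <- glance(loocv_metrics(x))
  dplyr::bind_cols(
    tibble::tibble(
      n_folds = x$n_folds, n_obs = nrow(x$oof),
      accuracy = mean(as.character(x$oof$label) ==
                        as.character(x$oof$predicted))),
    m)
}
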