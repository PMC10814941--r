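#' ggplot2 views of the evaluation results
#'
#' @name plots
NULL

#' Confusion-matrix heatmap
#'
#' Tile shading by count with the row-wise proportion printed in each cell.
#'
#' @param x A `bcc_metrics` object (or a confusion matrix).
#' @return A ggplot object.
#' @export
plot_confusion <- function(x) {
  cm <- if (inherits(x, "bcc_metrics")) x$confusion else as.matrix(x)
  df <- tibble::as_tibble(as.data.frame(as.table(cm)))
  names(df) <- c("truth", "predicted", "count")
  df <- dplyr::group_by(df, .data$truth)
  df <- dplyr::mutate(df, prop = ifelse(sum(.data$count) > 0,
                                        .data$count / sum(.data$count), 0))
  df <- dplyr::ungroup(df)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%d\n%.2f", .data$count, .data$prop)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "predicted class", y = "true class", fill = "n") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' FNR / FPR against the probability threshold, per class
#'
#' @param x A `bcc_loocv` object or a [threshold_curves()] tibble.
#' @return A ggplot object (one panel per class).
#' @export
plot_threshold_curves <- function(x) {
  tc <- if (inherits(x, "bcc_loocv")) threshold_curves(x) else x
  long <- tidyr::pivot_longer(tc[c("class", "threshold", "fpr", "fnr")],
                              c("fpr", "fnr"),
                              names_to = "rate", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                     colour = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "probability threshold", y = "proportion",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves
#'
#' @param x A `bcc_loocv` object or a [roc_curves()] tibble.
#' @return A ggplot object.
#' @export
plot_roc_curves <- function(x) {
  rc <- if (inherits(x, "bcc_loocv")) roc_curves(x) else x
  ggplot2::ggplot(rc, ggplot2::aes(.data$fpr, .data$tpr,
                                   colour = .data$class)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Top-k feature importance bars
#'
#' @param importance A [feature_importance()] tibble.
#' @param top_n Number of features shown.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 25) {
  df <- utils::head(importance, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$importance, .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "gain importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion heatmap of a metric suite
#' @param object A `bcc_metrics` object.
#' @param ... Unused.
#' @method autoplot bcc_metrics
#' @export
autoplot.bcc_metrics <- function(object, ...) plot_confusion(object)

#' Confusion heatmap of a LOOCV run
#' @param object A `bcc_loocv` object.
#' @param ... Unused.
#' @method autoplot bcc_loocv
#' @export
autoplot.bcc_loocv <- function(object, ...) {
  plot_confusion(loocv_metrics(object))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
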