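#' Feature importance and Shapley-value attributions
#'
#' Two complementary views of what drives the classifier: loss-based (gain)
#' importance aggregated over all splits of the boosted ensemble, and local
#' TreeSHAP attributions that decompose each individual prediction margin
#' additively over the features.
#'
#' @name importance
NULL

#' Loss-based feature importance
#'
#' Gain importance of every feature the model was trained on; features never
#' chosen for a split (e.g. constant in training) have importance 0.
#'
#' @param model A `bcc_model`.
#' @return Tibble `feature`, `importance`, sorted decreasing, covering all
#'   training features.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "bcc_model"))
  imp <- xgboost::xgb.importance(model = model$booster)
  out <- tibble::tibble(feature = model$features, importance = 0)
  hit <- match(imp$Feature, out$feature)
  out$importance[hit[!is.na(hit)]] <- imp$Gain[!is.na(hit)]
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' Per-observation Shapley-value attributions
#'
#' TreeSHAP contributions of every feature to each observation's per-class
#' prediction margin. The attributions are additive: for every observation
#' and class, sum(attributions) + base value equals the model's raw margin
#' output.
#'
#' @param model A `bcc_model`.
#' @param newdata Data frame with the model's feature columns (same scaling
#'   as training).
#' @return Long tibble `obs`, `class`, `feature`, `value`; the per-class
#'   base values are attached as the `base_values` attribute and the margin
#'   reconstruction is available via [shap_additivity_residual()].
#' @export
shap_attributions <- function(model, newdata) {
  stopifnot(inherits(model, "bcc_model"))
  x <- as.matrix(newdata[model$features])
  contrib <- predict(model$booster, x, predcontrib = TRUE)
  # array: obs x class x (features + intercept)
  stopifnot(length(dim(contrib)) == 3L)
  nfeat <- length(model$features)
  vals <- contrib[, , seq_len(nfeat), drop = FALSE]
  base <- contrib[, , nfeat + 1L, drop = TRUE]
  long <- tibble::tibble(
    obs = rep(seq_len(nrow(x)), times = length(model$classes) * nfeat),
    class = rep(rep(model$classes, each = nrow(x)), times = nfeat),
    feature = rep(model$features, each = nrow(x) * length(model$classes)),
    value = as.numeric(vals))
  attr(long, "base_values") <- base
  attr(long, "margin") <- predict(model$booster, x, outputmargin = TRUE)
  long
}

#' Local-additivity residual of Shapley attributions
#'
#' Maximum absolute difference between (sum of attributions + base value)
#' and the model's raw margin, over all observations and classes. By the
#' Shapley efficiency property this is numerically zero.
#'
#' @param attributions Result of [shap_attributions()].
#' @return Scalar residual.
#' @export
shap_additivity_residual <- function(attributions) {
  base <- attr(attributions, "base_values")
  margin <- attr(attributions, "margin")
  recon <- dplyr::summarise(
    dplyr::group_by(attributions, .data$obs, .data$class),
    total = sum(.data$value), .groups = "drop")
  recon <- tidyr::pivot_wider(recon, names_from = "class",
                              values_from = "total")
  recon <- dplyr::arrange(recon, .data$obs)
  classes <- unique(attributions$class)   # model class order
  recon <- as.matrix(recon[classes])
  max(abs(recon + base - margin))
}
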