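#' Gradient-boosted multiclass classification under tumor-grouped LOOCV
#'
#' The classifier is a gradient-boosted decision-tree ensemble with a softmax
#' multiclass loss, per-observation inverse-frequency class weights and early
#' stopping on a stratified slice of the training fold. Evaluation uses
#' leave-one-out cross-validation grouped by tumor: every fold removes all
#' observations of one tumor from training and predicts them out of fold, so
#' within-tumor correlation can never leak into the accuracy estimate.
#'
#' @name classify
NULL

#' Classifier and evaluation configuration
#'
#' @param depth Tree depth.
#' @param learning_rate Shrinkage per boosting round.
#' @param nrounds Maximum boosting rounds.
#' @param early_stopping_rounds Stop after this many non-improving rounds on
#'   the validation slice (the overfitting detector).
#' @param validation_fraction Fraction of training rows held out (stratified
#'   by class) for early stopping.
#' @param threshold_step Grid step for the probability-threshold curves.
#' @param scaling `"per_fold"` fits min-max scaling on each training fold
#'   only (leakage-free); `"global"` reproduces the literal
#'   scale-before-analysis reading.
#' @param seed Integer seed controlling the validation split and the
#'   booster's own randomness.
#' @return A `boost_config` list.
#' @export
boost_config <- function(depth = 4L, learning_rate = 0.1, nrounds = 500L,
                         early_stopping_rounds = 50L,
                         validation_fraction = 0.2,
                         threshold_step = 0.01,
                         scaling = c("per_fold", "global"),
                         seed = 1L) {
  structure(list(depth = as.integer(depth), learning_rate = learning_rate,
                 nrounds = as.integer(nrounds),
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 validation_fraction = validation_fraction,
                 threshold_step = threshold_step,
                 scaling = match.arg(scaling),
                 seed = as.integer(seed)),
            class = "boost_config")
}

# validation split for the overfitting detector. When tumor groups are
# known the slice is grouped by tumor (stratified by class at the tumor
# level, singleton-class tumors stay in training) so the detector measures
# tumor-level generalization, not within-tumor memorization; otherwise a
# plain class-stratified row split.
validation_indices <- function(labels, fraction, seed, groups = NULL) {
  if (fraction <= 0) return(integer(0))   # overfitting detector disabled
  withr::with_seed(seed, {
    if (!is.null(groups)) {
      tum <- unique(data.frame(group = groups, label = labels,
                               stringsAsFactors = FALSE))
      held <- unlist(lapply(split(tum$group, tum$label), function(g) {
        if (length(g) < 2L) return(character(0))
        n_val <- max(1L, floor(length(g) * fraction))
        if (n_val >= length(g)) n_val <- length(g) - 1L
        sample(g, n_val)
      }), use.names = FALSE)
      which(groups %in% held)
    } else {
      unlist(lapply(split(seq_along(labels), labels), function(ix) {
        if (length(ix) < 2L) return(integer(0))
        n_val <- max(1L, floor(length(ix) * fraction))
        if (n_val >= length(ix)) n_val <- length(ix) - 1L
        sample(ix, n_val)
      }), use.names = FALSE)
    }
  })
}

#' Train the boosted multiclass classifier
#'
#' @param train Fused feature tibble (`tumor_id`, `label`, `obs_idx` +
#'   features); feature columns are assumed already scaled.
#' @param weights A [class_weights()] tibble (computed on `train` when
#'   omitted).
#' @param config A [boost_config()].
#' @param features Feature columns to use.
#' @return A `bcc_model`: the fitted booster plus feature names and the
#'   class levels it predicts.
#' @export
train_classifier <- function(train, weights = class_weights(train$label),
                             config = boost_config(),
                             features = feature_columns(train)) {
  labels_chr <- as.character(train$label)
  classes <- diagnosis_levels()[diagnosis_levels() %in% unique(labels_chr)]
  if (length(classes) < 2L) {
    rlang::abort("training fold contains a single class: untrainable",
                 class = "dermofuse_untrainable")
  }
  y <- match(labels_chr, classes) - 1L
  w <- weights$weight[match(labels_chr, weights$label)]
  w[is.na(w)] <- 1
  x <- as.matrix(train[features])
  groups <- if ("tumor_id" %in% names(train)) train$tumor_id else NULL
  val_ix <- validation_indices(labels_chr, config$validation_fraction,
                               config$seed, groups)
  tr_ix <- setdiff(seq_len(nrow(x)), val_ix)
  params <- xgboost::xgb.params(
    objective = "multi:softprob", num_class = length(classes),
    max_depth = config$depth, learning_rate = config$learning_rate,
    nthread = 1, seed = config$seed)
  dtrain <- xgboost::xgb.DMatrix(x[tr_ix, , drop = FALSE], label = y[tr_ix],
                                 weight = w[tr_ix], nthread = 1)
  evals <- list(train = dtrain)
  if (length(val_ix) > 0L && length(unique(y[val_ix])) >= 1L) {
    evals$validation <- xgboost::xgb.DMatrix(
      x[val_ix, , drop = FALSE], label = y[val_ix], weight = w[val_ix],
      nthread = 1)
  }
  booster <- xgboost::xgb.train(
    params, dtrain, nrounds = config$nrounds, evals = evals,
    early_stopping_rounds = if (!is.null(evals$validation))
      config$early_stopping_rounds else NULL,
    verbose = 0)
  structure(list(booster = booster, features = features, classes = classes,
                 config = config),
            class = "bcc_model")
}

#' Predict class probabilities
#'
#' @param object A `bcc_model`.
#' @param newdata Data frame with the model's feature columns (same scaling
#'   as training).
#' @param ... Unused.
#' @return Matrix of class probabilities over [diagnosis_levels()]; classes
#'   absent from the training fold get probability 0.
#' @export
predict.bcc_model <- function(object, newdata, ...) {
  p <- predict(object$booster, as.matrix(newdata[object$features]))
  p <- matrix(p, ncol = length(object$classes), byrow = FALSE)
  colnames(p) <- object$classes
  full <- matrix(0, nrow(p), length(diagnosis_levels()),
                 dimnames = list(NULL, diagnosis_levels()))
  full[, object$classes] <- p
  full
}

#' Tumor-grouped leave-one-out cross-validation
#'
#' One fold per tumor: all of that tumor's observations are test-only.
#' Min-max scaling and class weights are recomputed on each training fold
#' (unless `config$scaling == "global"`), then the booster is trained and
#' the held-out tumor's class probabilities are predicted out of fold.
#'
#' @param fused Fused feature tibble from [pair_modalities()].
#' @param config A [boost_config()].
#' @return A `bcc_loocv` object: tibble `oof` (`tumor_id`, `obs_idx`,
#'   `label`, `predicted`, one probability column `p_<class>` per class),
#'   the configuration, per-fold train/test tumor bookkeeping (for leakage
#'   audits) and any fold notes.
#' @export
loocv_by_tumor <- function(fused, config = boost_config()) {
  tumors <- unique(fused$tumor_id)
  if (length(tumors) < 3L) {
    rlang::abort("tumor-grouped LOOCV needs at least 3 tumors",
                 class = "dermofuse_invalid_table")
  }
  features <- feature_columns(fused)
  global_params <- if (config$scaling == "global")
    fit_minmax(fused, features) else NULL
  notes <- character(0)
  fold_log <- vector("list", length(tumors))
  oof <- purrr::map(tumors, function(tid) {
    test <- dplyr::filter(fused, .data$tumor_id == tid)
    train <- dplyr::filter(fused, .data$tumor_id != tid)
    fold_log[[match(tid, tumors)]] <<- list(
      test_tumor = tid, train_tumors = unique(train$tumor_id))
    lost <- setdiff(unique(as.character(fused$label)),
                    unique(as.character(train$label)))
    if (length(lost) > 0L) {
      notes <<- c(notes, sprintf(
        "fold %s: class(es) %s absent from training; fold proceeds without them",
        tid, paste(lost, collapse = ", ")))
    }
    params <- if (is.null(global_params)) fit_minmax(train, features) else
      global_params
    train_s <- apply_minmax(train, params)
    test_s <- apply_minmax(test, params)
    model <- train_classifier(train_s, class_weights(train_s$label), config,
                              features)
    probs <- predict(model, test_s)
    colnames(probs) <- paste0("p_", colnames(probs))
    dplyr::bind_cols(test[c("tumor_id", "obs_idx", "label")],
                     tibble::as_tibble(probs))
  })
  oof <- dplyr::bind_rows(oof)
  pcols <- paste0("p_", diagnosis_levels())
  oof$predicted <- factor(
    diagnosis_levels()[max.col(as.matrix(oof[pcols]), ties.method = "first")],
    levels = diagnosis_levels())
  oof <- dplyr::relocate(oof, "predicted", .after = "label")
  structure(list(oof = oof, config = config, n_folds = length(tumors),
                 folds = fold_log, notes = notes),
            class = "bcc_loocv")
}

#' @export
print.bcc_loocv <- function(x, ...) {
  cat("Tumor-grouped LOOCV:", x$n_folds, "folds,", nrow(x$oof),
      "out-of-fold observations\n")
  acc <- mean(as.character(x$oof$label) == as.character(x$oof$predicted))
  cat(sprintf("argmax accuracy %.3f\n", acc))
  if (length(x$notes) > 0L) cat(paste0("  note: ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}
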