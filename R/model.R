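# Risk models: gradient-boosted trees, the logistic baseline, stratified
# cross-validation folds and out-of-fold prediction.

#' Gradient-boosting hyperparameter configuration
#'
#' Defaults follow the study's a-priori choices: 200 boosting iterations at
#' a conservative learning rate of 0.05, tree depth 3, minimum leaf size of
#' 30 samples, 80% row subsampling and square-root feature selection per
#' split. No grid search is performed anywhere in the package.
#'
#' @param n_trees Number of boosting iterations.
#' @param learning_rate Shrinkage (> 0).
#' @param max_depth Maximum tree depth.
#' @param min_leaf Minimum samples per leaf (>= 1). Enforced through the
#'   booster's hessian bound: with logistic loss each row's hessian is at
#'   most 0.25, so requiring a child hessian sum of `min_leaf / 4`
#'   guarantees at least `min_leaf` samples per leaf.
#' @param row_subsample Fraction of training rows per iteration, in (0, 1].
#' @param feature_subsample_rule Currently only `"sqrt"`: each split
#'   considers `sqrt(p)` of the `p` features.
#' @param seed Integer seed; training is deterministic per seed.
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(n_trees = 200, learning_rate = 0.05, max_depth = 3,
                         min_leaf = 30, row_subsample = 0.8,
                         feature_subsample_rule = "sqrt", seed = 1L) {
  if (learning_rate <= 0) {
    abort_uroxai("`learning_rate` must be > 0.", "uroxai_validation_error")
  }
  if (row_subsample <= 0 || row_subsample > 1) {
    abort_uroxai("`row_subsample` must lie in (0, 1].", "uroxai_validation_error")
  }
  if (min_leaf < 1) {
    abort_uroxai("`min_leaf` must be >= 1.", "uroxai_validation_error")
  }
  if (!identical(feature_subsample_rule, "sqrt")) {
    abort_uroxai("Only the square-root feature subsample rule is supported.",
                 "uroxai_validation_error")
  }
  structure(list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
                 max_depth = as.integer(max_depth), min_leaf = as.integer(min_leaf),
                 row_subsample = row_subsample,
                 feature_subsample_rule = feature_subsample_rule,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each patient to one of `k` folds, stratified by outcome: within
#' each class the (seed-shuffled) patients are dealt round-robin, so per-fold
#' class counts differ by at most one patient from exact proportionality.
#'
#' @param outcomes 0/1 outcome vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return An integer vector of fold indices in `1..k`, with attribute
#'   `"k"`.
#' @export
#' @examples
#' table(stratified_folds(rbinom(100, 1, 0.85), k = 5, seed = 1))
stratified_folds <- function(outcomes, k = 5, seed = 1L) {
  check_binary_outcome(outcomes)
  if (k < 2) {
    abort_uroxai("`k` must be >= 2.", "uroxai_validation_error")
  }
  counts <- table(factor(outcomes, levels = c(0, 1)))
  if (any(counts < k)) {
    abort_uroxai(
      sprintf("Stratification impossible: class with %d member(s) < k = %d folds.",
              min(counts), k),
      "uroxai_stratification_error")
  }
  set.seed(seed)
  fold <- integer(length(outcomes))
  for (cls in c(0, 1)) {
    idx <- sample(which(outcomes == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(fold, k = as.integer(k))
}

prepare_matrix <- function(data, features) {
  miss <- setdiff(features, names(data))
  if (length(miss) > 0) {
    abort_uroxai(paste0("Features absent from data: ", paste(miss, collapse = ", "), "."),
                 "uroxai_schema_error")
  }
  m <- as.matrix(data[, features, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Fit the gradient-boosted tree risk model
#'
#' Thin wrapper around xgboost's binary-logistic booster with the
#' configuration of [model_config()]. The booster is the modelling
#' instrument; all evaluation and explanation machinery in this package is
#' implemented independently of it.
#'
#' @param data Training data frame containing `features` and the outcome.
#' @param features Character vector of predictor columns.
#' @param config A [model_config()].
#' @param outcome Name of the 0/1 outcome column.
#' @return An object of class `"uro_gbm"`; use `predict(model, newdata)` for
#'   probabilities.
#' @export
fit_tree_ensemble <- function(data, features, config = model_config(),
                              outcome = "outcome") {
  y <- data[[outcome]]
  check_binary_outcome(y)
  if (length(unique(y)) < 2) {
    abort_uroxai("Training outcomes contain a single class; cannot fit.",
                 "uroxai_fit_error")
  }
  x <- prepare_matrix(data, features)
  p <- length(features)
  set.seed(config$seed)
  params <- list(
    objective = "binary:logistic",
    eta = config$learning_rate,
    max_depth = config$max_depth,
    min_child_weight = config$min_leaf / 4,
    subsample = config$row_subsample,
    colsample_bynode = max(sqrt(p) / p, 1 / p),
    nthread = 1,
    seed = config$seed
  )
  booster <- xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = config$n_trees,
    verbose = 0
  )
  structure(list(booster = booster, features = features, config = config,
                 outcome = outcome),
            class = "uro_gbm")
}

#' @export
predict.uro_gbm <- function(object, newdata, ...) {
  x <- prepare_matrix(newdata, object$features)
  as.numeric(predict(object$booster, xgboost::xgb.DMatrix(x)))
}

#' Fit the standardized logistic-regression baseline
#'
#' Plain logistic regression on the same features, with every predictor
#' standardized to zero mean and unit variance using training-row statistics
#' only. Constant columns are dropped (an all-constant design yields the
#' intercept-only model, i.e. the class rate).
#'
#' @inheritParams fit_tree_ensemble
#' @return An object of class `"uro_logit"`.
#' @export
fit_logistic_baseline <- function(data, features, outcome = "outcome") {
  y <- data[[outcome]]
  check_binary_outcome(y)
  if (length(unique(y)) < 2) {
    abort_uroxai("Training outcomes contain a single class; cannot fit.",
                 "uroxai_fit_error")
  }
  x <- prepare_matrix(data, features)
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  keep <- sg > 0
  xs <- scale(x[, keep, drop = FALSE], center = mu[keep], scale = sg[keep])
  df <- as.data.frame(xs)
  df$.y <- y
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  structure(list(fit = fit, features = features, keep = keep,
                 center = mu, scale = sg, outcome = outcome),
            class = "uro_logit")
}

#' @export
predict.uro_logit <- function(object, newdata, ...) {
  x <- prepare_matrix(newdata, object$features)
  xs <- scale(x[, object$keep, drop = FALSE],
              center = object$center[object$keep],
              scale = object$scale[object$keep])
  as.numeric(predict(object$fit, newdata = as.data.frame(xs), type = "response"))
}

fit_model <- function(data, features, config, model, outcome = "outcome") {
  switch(model,
    gbm = fit_tree_ensemble(data, features, config, outcome),
    logistic = fit_logistic_baseline(data, features, outcome),
    abort_uroxai(sprintf("Unknown model type `%s`.", model),
                 "uroxai_validation_error")
  )
}

#' Out-of-fold predictions under stratified cross-validation
#'
#' For each fold, the model is trained on the remaining folds and predicts
#' the held-out patients, so every patient's probability comes from a model
#' that never saw that patient in training. Fold assignment is recorded for
#' auditability.
#'
#' @param data Cohort data frame.
#' @param features Predictor columns.
#' @param config A [model_config()]; each fold's model derives its training
#'   seed from `config$seed` and the fold index, independent of the feature
#'   subset, so identical folds and seeds give reproducible stage models.
#' @param folds Fold assignment from [stratified_folds()].
#' @param model `"gbm"` or `"logistic"`.
#' @param tag Model tag stored alongside the predictions.
#' @param outcome Name of the outcome column.
#' @return A tibble with columns `patient_id`, `fold`, `p`, `outcome`,
#'   `model`.
#' @export
oof_predict <- function(data, features, config = model_config(), folds,
                        model = "gbm", tag = model, outcome = "outcome") {
  n <- nrow(data)
  if (length(folds) != n) {
    abort_uroxai("`folds` must assign every patient exactly once.",
                 "uroxai_validation_error")
  }
  k <- attr(folds, "k") %||% max(folds)
  if (k < 2) {
    abort_uroxai("`k` must be >= 2 for out-of-fold prediction.",
                 "uroxai_validation_error")
  }
  p <- numeric(n)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("fold", f))
    fitted <- tryCatch(
      fit_model(data[train_idx, , drop = FALSE], features, cfg, model, outcome),
      error = function(e) {
        abort_uroxai(sprintf("Model fit failed in fold %d: %s", f, conditionMessage(e)),
                     "uroxai_fit_error")
      })
    p[test_idx] <- predict(fitted, data[test_idx, , drop = FALSE])
  }
  tibble::tibble(
    patient_id = data$patient_id %||% seq_len(n),
    fold = as.integer(folds),
    p = p,
    outcome = as.numeric(data[[outcome]]),
    model = tag
  )
}
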