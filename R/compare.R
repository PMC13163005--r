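# Paired model comparison (DeLong, paired bootstrap) and held-out
# permutation importance.

# Placement values: for each positive, the fraction of negatives it beats
# (ties half); for each negative, the fraction of positives it loses to.
placement_values <- function(p, outcome) {
  pos <- p[outcome == 1]
  neg <- p[outcome == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  v10 <- vapply(pos, function(x) (sum(x > neg) + 0.5 * sum(x == neg)) / n0,
                numeric(1))
  v01 <- vapply(neg, function(y) (sum(pos > y) + 0.5 * sum(pos == y)) / n1,
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for paired correlated AUCs
#'
#' Compares the AUCs of two models evaluated on the same patients using the
#' asymptotic normal theory of per-observation placement values. Identical
#' prediction vectors give a difference of exactly zero and a p-value of
#' exactly 1; the statistic is antisymmetric in the two models.
#'
#' @param preds_a,preds_b Prediction tables (columns `p`, `outcome`, and
#'   `patient_id` if available) for the two models, over the same patients
#'   in the same order.
#' @return A one-row tibble: `auc_a`, `auc_b`, `delta_auc`, `se`, `z`,
#'   `p_value`.
#' @export
delong_test <- function(preds_a, preds_b) {
  a <- as_pred_frame(preds_a)
  b <- as_pred_frame(preds_b)
  if (nrow(a) != nrow(b) || !all(a$outcome == b$outcome)) {
    abort_uroxai("DeLong test needs paired predictions: same patients and outcomes.",
                 "uroxai_validation_error")
  }
  if (is.data.frame(preds_a) && is.data.frame(preds_b) &&
      "patient_id" %in% names(preds_a) && "patient_id" %in% names(preds_b) &&
      !all(preds_a$patient_id == preds_b$patient_id)) {
    abort_uroxai("DeLong test needs paired predictions: patient ids differ.",
                 "uroxai_validation_error")
  }
  check_binary_outcome(a$outcome)
  pa <- placement_values(a$p, a$outcome)
  pb <- placement_values(b$p, b$outcome)
  n1 <- length(pa$v10)
  n0 <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
               (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$auc - pb$auc
  if (delta == 0 && var_delta <= 0) {
    z <- 0
  } else {
    z <- delta / sqrt(var_delta)
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta,
                 se = sqrt(max(var_delta, 0)), z = z,
                 p_value = 2 * pnorm(-abs(z)))
}

# DeLong variance of a single AUC, used in variance cross-checks.
delong_auc_variance <- function(p, outcome) {
  pl <- placement_values(p, outcome)
  stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
}

#' Paired bootstrap for an AUC difference
#'
#' Resamples patients with replacement (stratified by outcome class) and
#' recomputes both models' AUCs on every resample. Reports the mean
#' difference, a percentile confidence interval, and a two-sided p-value
#' `2 * min(frac(delta* <= 0), frac(delta* >= 0))` clipped to `[1/B, 1]`.
#'
#' @inheritParams delong_test
#' @param B Number of resamples.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A one-row tibble: `delta_auc`, `mean_delta`, `lo`, `hi`,
#'   `p_value`, `b`.
#' @export
paired_bootstrap_delta_auc <- function(preds_a, preds_b, B = 2000, seed = 1L,
                                       level = 0.95) {
  a <- as_pred_frame(preds_a)
  b <- as_pred_frame(preds_b)
  if (nrow(a) != nrow(b) || !all(a$outcome == b$outcome)) {
    abort_uroxai("Paired bootstrap needs paired predictions.",
                 "uroxai_validation_error")
  }
  check_binary_outcome(a$outcome)
  ip <- which(a$outcome == 1)
  in_ <- which(a$outcome == 0)
  n1 <- length(ip)
  n0 <- length(in_)
  set.seed(seed)
  fast_auc <- function(s, n1, n0) {
    r <- rank(s)
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  deltas <- vapply(seq_len(B), function(i) {
    idx <- c(ip[sample.int(n1, n1, replace = TRUE)],
             in_[sample.int(n0, n0, replace = TRUE)])
    fast_auc(a$p[idx], n1, n0) - fast_auc(b$p[idx], n1, n0)
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- quantile(deltas, c(alpha, 1 - alpha), names = FALSE)
  pv <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  tibble::tibble(delta_auc = roc_auc(a) - roc_auc(b),
                 mean_delta = mean(deltas), lo = ci[1], hi = ci[2],
                 p_value = min(max(pv, 1 / B), 1), b = as.integer(B))
}

#' Held-out permutation feature importance
#'
#' For every cross-validation fold, the model trained on the other folds
#' predicts the held-out split; each feature's test-split column is then
#' permuted `repeats` times and the drop in held-out AUC recorded. Reported
#' per feature as the mean and standard deviation, across folds, of the
#' fold-level mean AUC drop. Computing on held-out rows makes the score an
#' out-of-sample importance, not an in-sample fit diagnostic.
#'
#' @inheritParams oof_predict
#' @param repeats Permutation repeats per fold.
#' @param seed Integer seed for the permutations.
#' @return A tibble sorted by decreasing importance: `feature`,
#'   `mean_delta_auc`, `sd_delta_auc`.
#' @export
permutation_importance_heldout <- function(data, features,
                                           config = model_config(), folds,
                                           repeats = 30, seed = 1L,
                                           model = "gbm", outcome = "outcome") {
  if (repeats < 1) {
    abort_uroxai("`repeats` must be >= 1.", "uroxai_validation_error")
  }
  k <- attr(folds, "k") %||% max(folds)
  per_fold <- matrix(NA_real_, nrow = k, ncol = length(features),
                     dimnames = list(NULL, features))
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, paste0("fold", f))
    fitted <- fit_model(data[folds != f, , drop = FALSE], features, cfg,
                        model, outcome)
    test <- data[test_idx, , drop = FALSE]
    y <- test[[outcome]]
    auc0 <- roc_auc(predict(fitted, test), y)
    for (j in seq_along(features)) {
      set.seed(derive_seed(seed, paste0("perm_f", f, "_", features[j])))
      drops <- vapply(seq_len(repeats), function(r) {
        perm <- test
        perm[[features[j]]] <- perm[[features[j]]][sample.int(nrow(perm))]
        roc_auc(predict(fitted, perm), y)
      }, numeric(1))
      per_fold[f, j] <- auc0 - mean(drops)
    }
  }
  tibble::tibble(
    feature = features,
    mean_delta_auc = colMeans(per_fold),
    sd_delta_auc = apply(per_fold, 2, sd)
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_delta_auc))
}
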