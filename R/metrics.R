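# Discrimination and calibration metrics, implemented in-repo.

#' Mann-Whitney AUC with midrank tie handling
#'
#' The area under the ROC curve computed as the probability that a random
#' positive outscores a random negative, with ties credited one half — the
#' midrank convention the DeLong machinery assumes.
#'
#' @param p Predicted probabilities (or any monotone scores), or a
#'   prediction table with columns `p` and `outcome`.
#' @param outcome 0/1 outcomes when `p` is a vector.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.2, 0.4, 0.4, 0.7), c(0, 1, 0, 1))  # 0.875
roc_auc <- function(p, outcome = NULL) {
  d <- as_pred_frame(p, outcome)
  check_binary_outcome(d$outcome)
  n1 <- sum(d$outcome == 1)
  n0 <- sum(d$outcome == 0)
  if (n1 == 0 || n0 == 0) {
    abort_uroxai("AUC needs both outcome classes.", "uroxai_validation_error")
  }
  r <- rank(d$p)  # midranks
  (sum(r[d$outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the 0/1
#' outcome. The constant predictor at the prevalence scores exactly
#' `pi * (1 - pi)`.
#'
#' @inheritParams roc_auc
#' @return Non-negative real.
#' @export
brier_score <- function(p, outcome = NULL) {
  d <- as_pred_frame(p, outcome)
  mean((d$p - d$outcome)^2)
}

#' Class-stratified bootstrap confidence interval for the AUC
#'
#' Resamples patients with replacement within each outcome class (so no
#' resample is ever single-class, which matters at 85% prevalence) and
#' reports the percentile interval of the resampled AUCs.
#'
#' @inheritParams roc_auc
#' @param B Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A one-row tibble: `auc`, `lo`, `hi`, `b`.
#' @export
bootstrap_auc_ci <- function(p, outcome = NULL, B = 1000, seed = 1L,
                             level = 0.95) {
  d <- as_pred_frame(p, outcome)
  check_binary_outcome(d$outcome)
  pos <- d$p[d$outcome == 1]
  neg <- d$p[d$outcome == 0]
  n1 <- length(pos)
  n0 <- length(neg)
  set.seed(seed)
  y <- c(rep(1, n1), rep(0, n0))
  stats <- vapply(seq_len(B), function(b) {
    s <- c(pos[sample.int(n1, n1, replace = TRUE)],
           neg[sample.int(n0, n0, replace = TRUE)])
    r <- rank(s)
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- quantile(stats, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(auc = roc_auc(d), lo = ci[1], hi = ci[2], b = as.integer(B))
}

#' Quantile-binned calibration table
#'
#' Bins patients by quantiles of predicted probability and reports, per
#' bin, the mean prediction and the observed event rate. Tied predictions
#' collapse bins (all-equal predictions occupy a single bin); counts always
#' sum to the number of patients.
#'
#' @inheritParams roc_auc
#' @param n_bins Target number of quantile bins.
#' @return A tibble: `bin`, `n`, `mean_p`, `obs_rate`.
#' @export
calibration_table <- function(p, outcome = NULL, n_bins = 10) {
  d <- as_pred_frame(p, outcome)
  br <- unique(quantile(d$p, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2) br <- c(br - 1e-12, br + 1e-12)
  bin <- cut(d$p, breaks = br, include.lowest = TRUE, labels = FALSE)
  d |>
    dplyr::mutate(bin = bin) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(n = dplyr::n(), mean_p = mean(.data$p),
                     obs_rate = mean(.data$outcome), .groups = "drop") |>
    structure(class = c("uro_calibration", class(tibble::tibble())))
}

#' Observed prevalence by predicted-probability stratum
#'
#' Stratifies patients into half-open probability intervals `[lo, hi)` (the
#' last interval closed above) and reports per-stratum counts and observed
#' outcome prevalence.
#'
#' @inheritParams roc_auc
#' @param edges Increasing vector of stratum boundaries spanning `[0, 1]`,
#'   e.g. `c(0, 0.5, 0.7, 0.85, 1)`.
#' @return A tibble: `stratum`, `lo`, `hi`, `n`, `prevalence`.
#' @export
risk_strata_table <- function(p, outcome = NULL, edges = c(0, 0.5, 0.7, 0.85, 1)) {
  d <- as_pred_frame(p, outcome)
  if (is.unsorted(edges, strictly = TRUE)) {
    abort_uroxai("`edges` must be strictly increasing.", "uroxai_validation_error")
  }
  k <- length(edges) - 1
  idx <- findInterval(d$p, edges, rightmost.closed = TRUE, all.inside = TRUE)
  out <- tibble::tibble(
    stratum = sprintf("[%.2f, %.2f%s", edges[-length(edges)], edges[-1],
                      c(rep(")", k - 1), "]")),
    lo = edges[-length(edges)],
    hi = edges[-1],
    n = vapply(seq_len(k), function(i) sum(idx == i), integer(1)),
    prevalence = vapply(seq_len(k), function(i) {
      if (any(idx == i)) mean(d$outcome[idx == i]) else NA_real_
    }, numeric(1))
  )
  out
}
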