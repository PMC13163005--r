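# Threshold operating points and Bayes prevalence projection of predictive
# values.

#' Operating point of a probability threshold
#'
#' Applies a probability threshold to out-of-fold predictions as a binary
#' test and records the 2x2 table with its sensitivity and specificity.
#' The high arm calls a patient test-positive when `p >= tau`; the low arm
#' calls a patient test-negative when `p <= tau` (boundary included, unlike
#' the cascade's strict inequalities — a deliberate, documented
#' difference).
#'
#' @inheritParams roc_auc
#' @param tau Probability threshold.
#' @param arm `"high"` or `"low"`.
#' @return A one-row tibble: `arm`, `tau`, `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `specificity` (either may be `NA` if a class is empty).
#' @export
operating_point <- function(p, outcome = NULL, tau, arm = c("high", "low")) {
  arm <- match.arg(arm)
  d <- as_pred_frame(p, outcome)
  check_binary_outcome(d$outcome)
  check_prob(tau, "tau")
  test_pos <- if (arm == "high") d$p >= tau else d$p > tau
  tp <- sum(test_pos & d$outcome == 1)
  fp <- sum(test_pos & d$outcome == 0)
  fn <- sum(!test_pos & d$outcome == 1)
  tn <- sum(!test_pos & d$outcome == 0)
  se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (fp + tn > 0) tn / (fp + tn) else NA_real_
  tibble::tibble(arm = arm, tau = tau, tp = tp, fn = fn, fp = fp, tn = tn,
                 sensitivity = se, specificity = sp)
}

#' Project predictive values to another prevalence via Bayes' rule
#'
#' `PPV = Se * pi / (Se * pi + (1 - Sp)(1 - pi))` and
#' `NPV = Sp (1 - pi) / (Sp (1 - pi) + (1 - Se) pi)`. Evaluating at the
#' source cohort's own prevalence reproduces the empirical PPV/NPV exactly
#' (closed-loop identity).
#'
#' @param op An [operating_point()] row.
#' @param prevalence Target prevalence(s) in (0, 1); vectorized.
#' @return A tibble: `prevalence`, `ppv`, `npv`.
#' @export
#' @examples
#' op <- tibble::tibble(sensitivity = 0.8, specificity = 0.9)
#' project_ppv_npv(op, 0.3)  # PPV 0.774, NPV 0.913
project_ppv_npv <- function(op, prevalence) {
  for (pv in prevalence) check_prob(pv, "prevalence", open = TRUE)
  se <- op$sensitivity
  sp <- op$specificity
  if (is.na(se) || is.na(sp)) {
    abort_uroxai("Operating point has undefined sensitivity or specificity.",
                 "uroxai_degenerate_error")
  }
  den_p <- se * prevalence + (1 - sp) * (1 - prevalence)
  den_n <- sp * (1 - prevalence) + (1 - se) * prevalence
  tibble::tibble(
    prevalence = prevalence,
    ppv = ifelse(den_p > 0, se * prevalence / den_p, NA_real_),
    npv = ifelse(den_n > 0, sp * (1 - prevalence) / den_n, NA_real_)
  )
}

#' Prevalence projection grid for a threshold pair
#'
#' Evaluates the high-arm operating point's PPV and the low-arm operating
#' point's NPV over a grid of baseline prevalences, together with the
#' likelihood ratios `LR+ = Se / (1 - Sp)` (high arm) and
#' `LR- = (1 - Se) / Sp` (low arm). For `LR+ > 1` the PPV is non-decreasing
#' and for `LR- < 1` the NPV is non-increasing in prevalence.
#'
#' @param op_high High-arm [operating_point()].
#' @param op_low Low-arm [operating_point()].
#' @param grid Prevalence grid in (0, 1).
#' @return An object of class `"uro_projection"`: tibble with `prevalence`,
#'   `ppv_high`, `npv_low`, `lr_pos`, `lr_neg`.
#' @export
projection_table <- function(op_high, op_low, grid = seq(0.05, 0.95, by = 0.05)) {
  hi <- project_ppv_npv(op_high, grid)
  lo <- project_ppv_npv(op_low, grid)
  lr_pos <- if (op_high$specificity < 1) {
    op_high$sensitivity / (1 - op_high$specificity)
  } else Inf
  lr_neg <- if (op_low$specificity > 0) {
    (1 - op_low$sensitivity) / op_low$specificity
  } else Inf
  out <- tibble::tibble(prevalence = grid, ppv_high = hi$ppv, npv_low = lo$npv,
                        lr_pos = lr_pos, lr_neg = lr_neg)
  class(out) <- c("uro_projection", class(tibble::tibble()))
  out
}
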