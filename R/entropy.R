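# Shannon-entropy sequential information gain and the threshold-based
# resolution cascade.

#' Binary Shannon entropy in bits
#'
#' `H(p) = -p log2(p) - (1 - p) log2(1 - p)`, with the `0 * log 0 = 0`
#' convention at the boundaries (no probability clipping). Symmetric about
#' `p = 0.5`, where it reaches its 1-bit maximum.
#'
#' @param p Probabilities in `[0, 1]` (vectorized).
#' @return Entropies in `[0, 1]` bits.
#' @export
#' @examples
#' binary_entropy(c(0.5, 0.85))  # 1.000, 0.610
binary_entropy <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort_uroxai("`p` must lie in [0, 1].", "uroxai_domain_error")
  }
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Prior entropy of a cohort
#'
#' The diagnostic uncertainty a clinician faces before any testing: the
#' binary entropy of the observed outcome prevalence.
#'
#' @param outcomes 0/1 outcome vector.
#' @return A one-row tibble: `prevalence`, `h0` (bits).
#' @export
prior_entropy <- function(outcomes) {
  check_binary_outcome(outcomes)
  prev <- mean(outcomes)
  tibble::tibble(prevalence = prev, h0 = binary_entropy(prev))
}

#' Entropy-gain arithmetic over a sequence of stage entropies
#'
#' Given the mean per-stage entropies and the prior entropy, computes each
#' stage's marginal information gain (entropy reduction relative to the
#' previous stage, as a percentage of the prior entropy) and the cumulative
#' gain. The marginal values telescope: they sum exactly to the cumulative
#' value before any rounding.
#'
#' @param mean_h Vector of per-stage mean entropies (bits), stage order.
#' @param h0 Prior entropy (bits).
#' @return A tibble: `stage`, `mean_h`, `marginal_dh_pct`,
#'   `cumulative_dh_pct`.
#' @export
#' @examples
#' entropy_gain_table(c(0.521, 0.509, 0.469, 0.461, 0.444), h0 = 0.610)
entropy_gain_table <- function(mean_h, h0) {
  if (h0 <= 0) {
    abort_uroxai("`h0` must be positive.", "uroxai_domain_error")
  }
  prev <- c(h0, head(mean_h, -1))
  tibble::tibble(
    stage = seq_along(mean_h),
    mean_h = mean_h,
    marginal_dh_pct = 100 * (prev - mean_h) / h0,
    cumulative_dh_pct = 100 * (h0 - mean_h) / h0
  )
}

#' Fit the five stage-specific models and collect out-of-fold predictions
#'
#' One model per testing stage, trained on the cumulative feature set
#' available at that stage with the same hyperparameters as the full model,
#' evaluated on the held-out folds of one shared stratified fold
#' assignment. Because fold training seeds do not depend on the feature
#' subset, the final stage reproduces the full-feature model's out-of-fold
#' run exactly.
#'
#' @param data Cohort data frame.
#' @param stages Stage table from [stage_definitions()].
#' @param config A [model_config()].
#' @param folds Shared fold assignment from [stratified_folds()].
#' @param model `"gbm"` or `"logistic"`.
#' @return A tibble of stacked per-stage predictions: `stage`, `label`,
#'   `n_features`, `patient_id`, `fold`, `p`, `outcome`.
#' @export
fit_stage_models <- function(data, stages = stage_definitions(),
                             config = model_config(), folds, model = "gbm") {
  validate_stages(stages)
  purrr::map_dfr(seq_len(nrow(stages)), function(i) {
    oof <- oof_predict(data, stages$features[[i]], config, folds,
                       model = model, tag = stages$label[i])
    tibble::tibble(stage = stages$stage[i], label = stages$label[i],
                   n_features = stages$n_features[i],
                   patient_id = oof$patient_id, fold = oof$fold,
                   p = oof$p, outcome = oof$outcome)
  })
}

#' Per-stage entropy and discrimination summary
#'
#' Mean entropy at each stage is computed over all patients (population
#' accounting, parallel to — not nested within — the resolution cascade),
#' with marginal and cumulative gains referenced to the prior entropy.
#'
#' @param stage_preds Stacked per-stage predictions from
#'   [fit_stage_models()].
#' @param h0 Prior entropy; defaults to the entropy of the observed
#'   prevalence.
#' @return A tibble: `stage`, `label`, `n_features`, `auc`, `mean_h`,
#'   `marginal_dh_pct`, `cumulative_dh_pct`.
#' @export
stage_entropy_summary <- function(stage_preds, h0 = NULL) {
  stages <- sort(unique(stage_preds$stage))
  if (is.null(h0)) {
    h0 <- prior_entropy(stage_preds$outcome[stage_preds$stage == stages[1]])$h0
  }
  per <- purrr::map_dfr(stages, function(s) {
    d <- stage_preds[stage_preds$stage == s, ]
    tibble::tibble(stage = s, label = d$label[1], n_features = d$n_features[1],
                   auc = roc_auc(d$p, d$outcome),
                   mean_h = mean(binary_entropy(d$p)))
  })
  gains <- entropy_gain_table(per$mean_h, h0)
  per$marginal_dh_pct <- gains$marginal_dh_pct
  per$cumulative_dh_pct <- gains$cumulative_dh_pct
  attr(per, "h0") <- h0
  per
}

#' Mean entropy trajectories by outcome class
#'
#' Per-stage mean entropy over confirmed-stone and non-stone patients
#' separately; in a high-prevalence cohort the two trajectories diverge,
#' reflecting that ruling in is structurally easier than ruling out.
#'
#' @inheritParams stage_entropy_summary
#' @return A tibble: `stage`, `outcome`, `n`, `mean_h`.
#' @export
trajectories_by_outcome <- function(stage_preds) {
  stage_preds |>
    dplyr::group_by(.data$stage, .data$outcome) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_h = mean(binary_entropy(.data$p)),
                     .groups = "drop")
}

#' Sequential threshold-based resolution cascade
#'
#' Scans stages in order; a patient resolves at the first stage where the
#' stage-specific out-of-fold probability strictly exceeds `tau_high`
#' (high-probability arm) or falls strictly below `tau_low` (low-probability
#' arm), keeps that classification, and is excluded from later stages.
#' Patients never reaching either threshold are unresolved after all
#' stages.
#'
#' @inheritParams stage_entropy_summary
#' @param tau_high High-probability threshold (default 0.90).
#' @param tau_low Low-probability threshold (default 0.20).
#' @return An object of class `"uro_cascade"`: list with `patients`
#'   (tibble: `patient_id`, `outcome`, `resolution_stage` — `NA` if
#'   unresolved — and `arm` in `high`/`low`/`none`), `by_stage` (tibble:
#'   `stage`, `newly_high`, `newly_low`, `cum_resolved`, `cum_fraction`,
#'   `unresolved_n`, `unresolved_prevalence`, plus cumulative-arm counts and
#'   outcome rates `rule_in_n`, `rule_in_stone_pct`, `low_n`,
#'   `low_stone_pct`), and the thresholds.
#' @export
sequential_resolution <- function(stage_preds, tau_high = 0.90, tau_low = 0.20) {
  if (!(tau_low > 0 && tau_low < tau_high && tau_high < 1)) {
    abort_uroxai("Thresholds must satisfy 0 < tau_low < tau_high < 1.",
                 "uroxai_validation_error")
  }
  stages <- sort(unique(stage_preds$stage))
  ids <- stage_preds$patient_id[stage_preds$stage == stages[1]]
  wide <- lapply(stages, function(s) {
    d <- stage_preds[stage_preds$stage == s, ]
    if (nrow(d) != length(ids) || !setequal(d$patient_id, ids)) {
      abort_uroxai("Patient sets differ across stages.", "uroxai_validation_error")
    }
    d[match(ids, d$patient_id), ]
  })
  outcome <- wide[[1]]$outcome
  n <- length(ids)
  res_stage <- rep(NA_integer_, n)
  arm <- rep("none", n)
  by_stage <- purrr::map_dfr(seq_along(stages), function(si) {
    p <- wide[[si]]$p
    open <- is.na(res_stage)
    hi <- open & p > tau_high
    lo <- open & p < tau_low
    res_stage[which(hi | lo)] <<- stages[si]
    arm[which(hi)] <<- "high"
    arm[which(lo)] <<- "low"
    unresolved <- is.na(res_stage)
    tibble::tibble(
      stage = stages[si],
      newly_high = sum(hi), newly_low = sum(lo),
      cum_resolved = sum(!unresolved),
      cum_fraction = mean(!unresolved),
      rule_in_n = sum(arm == "high"),
      rule_in_stone_pct = if (any(arm == "high")) 100 * mean(outcome[arm == "high"]) else NA_real_,
      low_n = sum(arm == "low"),
      low_stone_pct = if (any(arm == "low")) 100 * mean(outcome[arm == "low"]) else NA_real_,
      unresolved_n = sum(unresolved),
      unresolved_prevalence = if (any(unresolved)) mean(outcome[unresolved]) else NA_real_
    )
  })
  structure(
    list(patients = tibble::tibble(patient_id = ids, outcome = outcome,
                                   resolution_stage = res_stage, arm = arm),
         by_stage = by_stage, tau_high = tau_high, tau_low = tau_low),
    class = "uro_cascade")
}

#' Final cascade partition with outcome prevalences
#'
#' Summarizes a cascade's final state: the rule-in (high-arm), low-arm and
#' unresolved groups partition the cohort, and each group's size, fraction
#' and observed outcome prevalence are reported.
#'
#' @param cascade A [sequential_resolution()] result.
#' @return A tibble: `group`, `n`, `fraction`, `prevalence`.
#' @export
cascade_summary <- function(cascade) {
  if (!inherits(cascade, "uro_cascade")) {
    abort_uroxai("`cascade` must come from sequential_resolution().",
                 "uroxai_validation_error")
  }
  d <- cascade$patients
  grp <- factor(ifelse(d$arm == "high", "rule_in",
                       ifelse(d$arm == "low", "low_probability", "unresolved")),
                levels = c("rule_in", "low_probability", "unresolved"))
  d |>
    dplyr::mutate(group = grp) |>
    dplyr::group_by(.data$group, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     fraction = dplyr::n() / nrow(d),
                     prevalence = if (dplyr::n() > 0) mean(.data$outcome) else NA_real_,
                     .groups = "drop")
}

#' Combined stage report
#'
#' Joins the per-stage entropy/AUC summary with the cascade's cumulative
#' rule-in and low-probability counts, mirroring the columns of a sequential
#' information-gain table.
#'
#' @inheritParams stage_entropy_summary
#' @inheritParams sequential_resolution
#' @return A tibble with one row per stage.
#' @export
stage_report <- function(stage_preds, h0 = NULL, tau_high = 0.90,
                         tau_low = 0.20) {
  ent <- stage_entropy_summary(stage_preds, h0)
  casc <- sequential_resolution(stage_preds, tau_high, tau_low)
  dplyr::left_join(
    ent,
    casc$by_stage[, c("stage", "rule_in_n", "rule_in_stone_pct",
                      "low_n", "low_stone_pct")],
    by = "stage")
}
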