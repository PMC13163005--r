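#' Sequential testing stages of the ED urolithiasis workup
#'
#' Five strictly nested feature sets mirror the order in which bedside
#' information accrues: history/demographics, then physical examination,
#' dipstick urinalysis, urine microscopy, and blood tests. Cumulative sizes
#' are 5, 9, 12, 15 and 17 features.
#'
#' @param spec A [cohort_spec()] supplying feature names and families;
#'   defaults to the shipped configuration.
#' @return A tibble with columns `stage`, `label`, `features` (list-column
#'   of cumulative feature names) and `n_features`.
#' @export
#' @examples
#' stage_definitions()$n_features
stage_definitions <- function(spec = default_cohort_spec()) {
  tab <- spec_feature_table(spec)
  order_fam <- c("history", "physical", "dipstick", "microscopy", "blood")
  labels <- c("Stage 1: History", "Stage 2: +Physical", "Stage 3: +Dipstick",
              "Stage 4: +Microscopy", "Stage 5: +Blood")
  feats <- list()
  acc <- character(0)
  for (i in seq_along(order_fam)) {
    acc <- c(acc, tab$feature[tab$family == order_fam[i]])
    feats[[i]] <- acc
  }
  out <- tibble::tibble(
    stage = seq_along(order_fam),
    label = labels,
    features = feats,
    n_features = lengths(feats)
  )
  validate_stages(out)
  out
}

validate_stages <- function(stages) {
  for (i in seq_len(nrow(stages) - 1)) {
    a <- stages$features[[i]]
    b <- stages$features[[i + 1]]
    if (!all(a %in% b) || length(b) <= length(a)) {
      abort_uroxai("Stage feature lists must be strictly nested.",
                   "uroxai_validation_error")
    }
  }
  invisible(stages)
}

#' Default dichotomization cutoffs for the 9-feature binary model
#'
#' The reference bedside score uses nine dichotomized variables. The
#' creatinine cutoff (>= 0.92 mg/dL) and the pain-duration rule (< 8 h
#' scores 1) are the conventionally cited thresholds; the remaining
#' memberships and cutoffs are documented placeholders chosen from the same
#' variable pool, and are fully configuration-driven.
#'
#' @return A tibble with columns `feature`, `threshold`, `direction`
#'   (`"ge"`: indicator of `x >= threshold`; `"lt"`: indicator of
#'   `x < threshold`).
#' @export
default_binary_cutoffs <- function() {
  tibble::tribble(
    ~feature,             ~threshold, ~direction,
    "sex",                1,          "ge",
    "stone_history",      1,          "ge",
    "pain_duration_h",    8,          "lt",
    "nausea",             1,          "ge",
    "cva_tenderness",     1,          "ge",
    "occult_blood_grade", 1,          "ge",
    "le_grade",           1,          "ge",
    "urine_rbc_hpf",      5,          "ge",
    "creatinine_mgdl",    0.92,       "ge"
  )
}

#' Replace features by 0/1 indicators at predefined cutoffs
#'
#' Applies dichotomization rules of the form "1 if `x >= threshold`"
#' (`direction = "ge"`) or "1 if `x < threshold`" (`direction = "lt"`).
#' Listed features are replaced by their indicators; unlisted features are
#' dropped. `patient_id` and `outcome` are kept and row order is preserved.
#'
#' @param cohort A cohort tibble.
#' @param cutoffs A tibble with columns `feature`, `threshold`, `direction`;
#'   defaults to [default_binary_cutoffs()].
#' @return A cohort tibble with only the dichotomized features.
#' @export
binarize_features <- function(cohort, cutoffs = default_binary_cutoffs()) {
  miss <- setdiff(cutoffs$feature, names(cohort))
  if (length(miss) > 0) {
    abort_uroxai(paste0("Cutoff features absent from cohort: ",
                        paste(miss, collapse = ", "), "."),
                 "uroxai_schema_error")
  }
  out <- cohort[, intersect(c("patient_id", cutoffs$feature, "outcome"), names(cohort))]
  for (i in seq_len(nrow(cutoffs))) {
    f <- cutoffs$feature[i]
    x <- cohort[[f]]
    out[[f]] <- if (cutoffs$direction[i] == "ge") {
      as.numeric(x >= cutoffs$threshold[i])
    } else {
      as.numeric(x < cutoffs$threshold[i])
    }
  }
  out
}
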