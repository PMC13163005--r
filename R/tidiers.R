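# broom-style accessors for fitted objects and result bundles.

#' @exportS3Method generics::glance
glance.uro_gbm <- function(x, ...) {
  tibble::tibble(
    n_trees = x$config$n_trees,
    learning_rate = x$config$learning_rate,
    max_depth = x$config$max_depth,
    min_leaf = x$config$min_leaf,
    row_subsample = x$config$row_subsample,
    n_features = length(x$features),
    seed = x$config$seed
  )
}

#' @exportS3Method generics::tidy
tidy.uro_logit <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "z value"],
    p_value = co[, "Pr(>|z|)"]
  )
}

#' @exportS3Method generics::glance
glance.uro_logit <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$features),
    n_dropped_constant = sum(!x$keep),
    aic = stats::AIC(x$fit),
    deviance = stats::deviance(x$fit)
  )
}

#' @exportS3Method generics::tidy
tidy.uro_cascade <- function(x, ...) {
  x$by_stage
}

#' @exportS3Method generics::glance
glance.uro_cascade <- function(x, ...) {
  final <- x$by_stage[nrow(x$by_stage), ]
  tibble::tibble(
    tau_high = x$tau_high, tau_low = x$tau_low,
    resolved_fraction = final$cum_fraction,
    rule_in_n = final$rule_in_n,
    low_n = final$low_n,
    unresolved_n = final$unresolved_n,
    unresolved_prevalence = final$unresolved_prevalence
  )
}

#' @exportS3Method generics::tidy
tidy.uro_attr <- function(x, ...) {
  fts <- attr_features(x)
  tidyr::pivot_longer(tibble::as_tibble(x)[, c("patient_id", fts)],
                      cols = dplyr::all_of(fts),
                      names_to = "feature", values_to = "phi")
}

#' @exportS3Method generics::glance
glance.uro_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n = x$manifest$n, prevalence = x$manifest$prevalence,
                   h0 = x$prior$h0),
    tidyr::pivot_wider(x$model_reports[, c("model", "auc")],
                       names_from = "model", values_from = "auc",
                       names_prefix = "auc_"),
    tibble::tibble(
      cumulative_dh_pct = x$stage_report$cumulative_dh_pct[nrow(x$stage_report)],
      reconstruction_mean_abs_gap = x$reconstruction$mean_abs_gap)
  )
}
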