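# End-to-end orchestration: one config in, a reproducible report bundle out.

#' Pipeline run configuration
#'
#' Collects every constant the pipeline needs: the cohort source, the one
#' root seed all randomness derives from, the booster configuration, stage
#' definitions, cascade thresholds, background size, and resampling counts.
#'
#' @param cohort A [cohort_spec()] (cohort is generated) or a path to a
#'   cohort CSV (cohort is loaded).
#' @param seed Root seed; every randomized step derives its own seed from
#'   it via [derive_seed()].
#' @param model A [model_config()].
#' @param k Cross-validation folds.
#' @param stages Stage definitions; `NULL` for [stage_definitions()] built
#'   from the cohort spec.
#' @param thresholds,alt_thresholds Length-2 `c(tau_high, tau_low)` pairs
#'   for the resolution cascade.
#' @param background_m Background sample size for attribution.
#' @param bootstrap_b AUC bootstrap resamples.
#' @param paired_b Paired-bootstrap resamples.
#' @param perm_repeats Permutation-importance repeats per fold.
#' @param binary_cutoffs Cutoff table for the 9-feature binary model.
#' @param strata_edges Risk-stratum boundaries.
#' @param out_dir Optional output directory for CSV/JSON/Markdown reports.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(cohort = default_cohort_spec(), seed = 1L,
                       model = model_config(), k = 5, stages = NULL,
                       thresholds = c(0.90, 0.20),
                       alt_thresholds = c(0.85, 0.30),
                       background_m = 100, bootstrap_b = 1000,
                       paired_b = 2000, perm_repeats = 30,
                       binary_cutoffs = default_binary_cutoffs(),
                       strata_edges = c(0, 0.5, 0.7, 0.85, 1),
                       out_dir = NULL) {
  if (any(c(bootstrap_b, paired_b, perm_repeats) < 1)) {
    abort_uroxai("Resampling counts must be >= 1.", "uroxai_validation_error")
  }
  structure(list(cohort = cohort, seed = as.integer(seed), model = model,
                 k = k, stages = stages, thresholds = thresholds,
                 alt_thresholds = alt_thresholds, background_m = background_m,
                 bootstrap_b = bootstrap_b, paired_b = paired_b,
                 perm_repeats = perm_repeats, binary_cutoffs = binary_cutoffs,
                 strata_edges = strata_edges, out_dir = out_dir),
            class = "run_config")
}

select_archetypes <- function(attr, preds) {
  fts <- attr_features(attr)
  phim <- as.matrix(attr[, fts, drop = FALSE])
  total_abs <- rowSums(abs(phim))
  total <- rowSums(phim)
  o <- preds$outcome[match(attr$patient_id, preds$patient_id)]
  p <- attr$.pred
  pick <- function(idx, score) {
    if (length(idx) == 0) return(NA_integer_)
    idx[which.max(score[idx])]
  }
  classic <- pick(which(o == 1), p)
  lowcase <- pick(which(o == 0), -p)
  conflicted <- {
    small_net <- which(abs(total) <= stats::median(abs(total)))
    pick(small_net, total_abs)
  }
  mimicker <- pick(which(o == 0), p)
  tibble::tibble(
    archetype = c("classic_stone", "low_probability", "conflicted", "mimicker"),
    patient_id = attr$patient_id[c(classic, lowcase, conflicted, mimicker)]
  )
}

#' Run the full diagnostic-reasoning pipeline
#'
#' Executes, in order: cohort generation (or loading); out-of-fold fitting
#' and evaluation of the four risk models (17-feature boosted trees,
#' 9-feature binary and continuous variants, standardized logistic
#' baseline) with bootstrap AUC intervals, Brier scores, calibration and
#' risk strata; DeLong and paired-bootstrap model comparisons; held-out
#' permutation importance; interventional attribution of a full-data refit
#' (global ranking, stratified contribution tables, dependence curves with
#' zero crossings, reconstruction error, four rule-selected archetype
#' waterfalls); the five-stage entropy report; resolution cascades at both
#' threshold pairs; and the prevalence projection grid. A manifest records
#' every derived seed. Two runs with the same config produce identical
#' numbers.
#'
#' @param config A [run_config()].
#' @return An object of class `"uro_run"` (a named list of tibbles and
#'   objects; see the methods vignette for a tour).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seeds <- list()
  note_seed <- function(label) {
    s <- derive_seed(config$seed, label)
    seeds[[label]] <<- s
    s
  }

  cohort <- if (inherits(config$cohort, "cohort_spec")) {
    spec <- config$cohort
    spec$seed <- note_seed("cohort")
    generate_cohort(spec)
  } else {
    read_cohort(config$cohort)
  }
  spec_for_meta <- if (inherits(config$cohort, "cohort_spec")) config$cohort else default_cohort_spec()
  features17 <- intersect(spec_feature_names(spec_for_meta), names(cohort))
  stages <- config$stages %||% stage_definitions(spec_for_meta)

  folds <- stratified_folds(cohort$outcome, k = config$k, seed = note_seed("folds"))
  base_cfg <- config$model
  base_cfg$seed <- note_seed("model")

  cohort_bin <- binarize_features(cohort, config$binary_cutoffs)
  model_defs <- list(
    feat17 = list(data = cohort, features = features17, model = "gbm"),
    feat9_continuous = list(data = cohort, features = config$binary_cutoffs$feature,
                            model = "gbm"),
    feat9_binary = list(data = cohort_bin, features = config$binary_cutoffs$feature,
                        model = "gbm"),
    logistic = list(data = cohort, features = features17, model = "logistic")
  )

  models <- purrr::imap(model_defs, function(def, tag) {
    oof <- oof_predict(def$data, def$features, base_cfg, folds,
                       model = def$model, tag = tag)
    ci <- bootstrap_auc_ci(oof, B = config$bootstrap_b,
                           seed = note_seed(paste0("bootstrap_", tag)))
    list(oof = oof,
         report = tibble::tibble(
           model = tag, auc = ci$auc, auc_lo = ci$lo, auc_hi = ci$hi,
           brier = brier_score(oof)),
         calibration = calibration_table(oof))
  })
  model_reports <- purrr::map_dfr(models, "report")

  comparisons <- dplyr::bind_rows(
    dplyr::mutate(delong_test(models$feat17$oof, models$feat9_binary$oof),
                  comparison = "feat17_vs_feat9_binary", method = "delong"),
    dplyr::mutate(delong_test(models$feat17$oof, models$logistic$oof),
                  comparison = "feat17_vs_logistic", method = "delong"),
    dplyr::bind_cols(
      paired_bootstrap_delta_auc(models$feat17$oof, models$logistic$oof,
                                 B = config$paired_b,
                                 seed = note_seed("paired_bootstrap")),
      tibble::tibble(comparison = "feat17_vs_logistic", method = "paired_bootstrap"))
  )

  importance <- permutation_importance_heldout(
    cohort, features17, base_cfg, folds, repeats = config$perm_repeats,
    seed = note_seed("importance"))

  strata <- risk_strata_table(models$feat17$oof, edges = config$strata_edges)

  # Explanations: full-data refit, per the default explanation target.
  refit_cfg <- base_cfg
  refit_cfg$seed <- note_seed("refit")
  refit <- fit_tree_ensemble(cohort, features17, refit_cfg)
  bg <- sample_background(cohort, m = config$background_m,
                          seed = note_seed("background"))
  attributions <- interventional_contributions(refit, cohort, bg)
  fts <- attr_features(attributions)
  global_ranking <- tibble::tibble(
    feature = fts,
    mean_abs_phi = colMeans(abs(as.matrix(attributions[, fts])))) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_phi))
  recon <- reconstruction_error(attributions)

  strata_tables <- list(
    creatinine_mgdl = stratified_contribution_table(
      attributions, cohort, "creatinine_mgdl", c(0.2, 0.70, 0.87, 0.92, 1.20, 3.5)),
    pain_duration_h = stratified_contribution_table(
      attributions, cohort, "pain_duration_h", c(0, 1, 2, 5, 16, 240)),
    crp_mgdl = stratified_contribution_table(
      attributions, cohort, "crp_mgdl", c(0, 0.5, 3, 50))
  )
  dep_features <- c("creatinine_mgdl", "pain_duration_h", "crp_mgdl", "age")
  dependence <- purrr::map(
    setNames(dep_features, dep_features),
    function(f) dependence_curve(attributions, cohort, f))
  crossings <- purrr::map_dfr(dep_features, function(f) {
    cr <- attr(dependence[[f]], "crossings")
    if (length(cr) == 0) return(tibble::tibble())
    tibble::tibble(feature = f, crossing = cr,
                   window = attr(dependence[[f]], "window"))
  })

  archetypes <- select_archetypes(attributions, models$feat17$oof)
  waterfalls <- purrr::map(
    setNames(archetypes$patient_id, archetypes$archetype),
    function(id) waterfall(attributions, id, cohort))

  # Sequential information gain and cascades.
  stage_preds <- fit_stage_models(cohort, stages, base_cfg, folds)
  h0 <- prior_entropy(cohort$outcome)
  stagerep <- stage_report(stage_preds, h0$h0,
                           tau_high = config$thresholds[1],
                           tau_low = config$thresholds[2])
  trajectories <- trajectories_by_outcome(stage_preds)
  cascade_default <- sequential_resolution(stage_preds,
                                           config$thresholds[1], config$thresholds[2])
  cascade_alt <- sequential_resolution(stage_preds,
                                       config$alt_thresholds[1], config$alt_thresholds[2])

  # Prevalence projection from the final-stage operating points.
  final_oof <- models$feat17$oof
  op_high <- operating_point(final_oof, tau = config$thresholds[1], arm = "high")
  op_low <- operating_point(final_oof, tau = config$thresholds[2], arm = "low")
  projection <- projection_table(op_high, op_low)

  manifest <- list(
    package_version = as.character(utils::packageVersion("uroxai")),
    root_seed = config$seed,
    derived_seeds = seeds,
    n = nrow(cohort),
    prevalence = mean(cohort$outcome),
    k = config$k,
    model = unclass(config$model),
    thresholds = config$thresholds,
    alt_thresholds = config$alt_thresholds,
    background_m = config$background_m,
    bootstrap_b = config$bootstrap_b,
    paired_b = config$paired_b,
    perm_repeats = config$perm_repeats
  )

  run <- structure(list(
    cohort = cohort,
    folds = folds,
    models = models,
    model_reports = model_reports,
    comparisons = comparisons,
    importance = importance,
    risk_strata = strata,
    attributions = attributions,
    global_ranking = global_ranking,
    reconstruction = recon,
    strata_tables = strata_tables,
    dependence = dependence,
    crossings = crossings,
    archetypes = archetypes,
    waterfalls = waterfalls,
    stage_preds = stage_preds,
    prior = h0,
    stage_report = stagerep,
    trajectories = trajectories,
    cascades = list(default = cascade_default, alternate = cascade_alt),
    cascade_summaries = list(default = cascade_summary(cascade_default),
                             alternate = cascade_summary(cascade_alt)),
    operating_points = dplyr::bind_rows(op_high, op_low),
    projection = projection,
    manifest = manifest
  ), class = "uro_run")

  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

#' Write a run's report bundle to disk
#'
#' Tables as CSV, the manifest and cascade summaries as JSON, and a short
#' human-readable Markdown summary.
#'
#' @param run A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_csv(x, file.path(out_dir, name))
  w(run$model_reports, "model_reports.csv")
  w(run$comparisons, "model_comparisons.csv")
  w(run$importance, "permutation_importance.csv")
  w(run$risk_strata, "risk_strata.csv")
  w(tibble::as_tibble(run$attributions), "attributions.csv")
  w(run$global_ranking, "global_ranking.csv")
  w(run$stage_report, "stage_report.csv")
  w(run$trajectories, "entropy_trajectories.csv")
  w(run$cascades$default$patients, "cascade_patients.csv")
  w(tibble::as_tibble(run$projection), "projection_grid.csv")
  for (f in names(run$strata_tables)) {
    w(run$strata_tables[[f]], paste0("strata_", f, ".csv"))
  }
  jsonlite::write_json(
    list(manifest = run$manifest,
         reconstruction_mean_abs_gap = run$reconstruction$mean_abs_gap,
         cascade_default = run$cascade_summaries$default,
         cascade_alternate = run$cascade_summaries$alternate),
    file.path(out_dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA)
  md <- c(
    "# uroxai run summary", "",
    sprintf("Cohort: n = %d, prevalence = %.3f, prior entropy = %.3f bits",
            run$manifest$n, run$prior$prevalence, run$prior$h0),
    "",
    "## Model discrimination",
    sprintf("- %s: AUC %.3f (%.3f-%.3f), Brier %.3f",
            run$model_reports$model, run$model_reports$auc,
            run$model_reports$auc_lo, run$model_reports$auc_hi,
            run$model_reports$brier),
    "",
    "## Sequential information gain",
    sprintf("- %s: mean H %.3f bits, marginal %.1f%%, cumulative %.1f%%",
            run$stage_report$label, run$stage_report$mean_h,
            run$stage_report$marginal_dh_pct, run$stage_report$cumulative_dh_pct),
    "",
    sprintf("Mean absolute attribution reconstruction error: %.4f",
            run$reconstruction$mean_abs_gap))
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}

#' @export
print.uro_run <- function(x, ...) {
  cat(sprintf("<uro_run> n = %d patients, prevalence %.3f\n",
              x$manifest$n, x$manifest$prevalence))
  cat("Models:\n")
  print(x$model_reports)
  cat("Stage report:\n")
  print(x$stage_report[, c("stage", "auc", "mean_h", "marginal_dh_pct",
                           "cumulative_dh_pct")])
  invisible(x)
}
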