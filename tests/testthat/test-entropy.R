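# Entropy arithmetic, stage models, trajectories and the resolution cascade.

test_that("binary entropy matches its closed form on a dense grid", {
  expect_equal(binary_entropy(0.5), 1.0)
  expect_equal(round(binary_entropy(0.85), 3), 0.610)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  grid <- seq(0, 1, length.out = 10000)
  direct <- ifelse(grid %in% c(0, 1), 0,
                   -grid * log2(grid) - (1 - grid) * log2(1 - grid))
  expect_lt(max(abs(binary_entropy(grid) - direct)), 1e-12)
  expect_equal(binary_entropy(grid), binary_entropy(1 - grid))
  expect_error(binary_entropy(1.1), class = "uroxai_domain_error")
  expect_error(binary_entropy(-0.01), class = "uroxai_domain_error")
})

test_that("prior entropy reflects the observed prevalence", {
  expect_equal(round(prior_entropy(rep(c(1, 0), c(85, 15)))$h0, 3), 0.610)
  expect_equal(prior_entropy(rep(c(1, 0), 50))$h0, 1.0)
  expect_equal(round(prior_entropy(rep(c(1, 0), c(40, 60)))$h0, 3), 0.971)
})

test_that("entropy gains telescope and match the stagewise arithmetic", {
  g <- entropy_gain_table(c(0.521, 0.509, 0.469, 0.461, 0.444), h0 = 0.610)
  expect_equal(round(g$marginal_dh_pct, 1), c(14.6, 2.0, 6.6, 1.3, 2.8))
  expect_equal(round(g$cumulative_dh_pct[5], 1), 27.2)
  expect_lt(max(abs(cumsum(g$marginal_dh_pct) - g$cumulative_dh_pct)), 1e-9)

  flat <- entropy_gain_table(rep(0.61, 5), h0 = 0.61)
  expect_equal(flat$marginal_dh_pct, rep(0, 5))
  expect_equal(flat$cumulative_dh_pct, rep(0, 5))
})

test_that("stage models share folds and the final stage equals the full model", {
  spec <- default_cohort_spec(n = 250, seed = 81)
  co <- generate_cohort(spec)
  folds <- stratified_folds(co$outcome, k = 3, seed = 82)
  cfg <- quick_config(seed = 83, n_trees = 30)
  stages <- stage_definitions(spec)
  sp <- fit_stage_models(co, stages, cfg, folds)
  expect_equal(sort(unique(sp$stage)), 1:5)
  expect_equal(unique(sp$n_features[sp$stage == 3]), 12)
  # every stage uses the same fold assignment
  for (s in 1:5) {
    expect_equal(sp$fold[sp$stage == s], as.integer(folds))
  }
  # stage 5 reproduces the 17-feature out-of-fold run under the same seed
  full <- oof_predict(co, stages$features[[5]], cfg, folds)
  expect_equal(sp$p[sp$stage == 5], full$p, tolerance = 1e-12)
})

test_that("stage summaries and trajectories use population accounting", {
  sp <- random_stage_preds(300, seed = 84, prevalence = 0.85)
  summ <- stage_entropy_summary(sp)
  expect_equal(nrow(summ), 5)
  h0 <- prior_entropy(sp$outcome[sp$stage == 1])$h0
  expect_equal(summ$cumulative_dh_pct, 100 * (h0 - summ$mean_h) / h0)
  expect_lt(max(abs(cumsum(summ$marginal_dh_pct) - summ$cumulative_dh_pct)), 1e-9)

  tr <- trajectories_by_outcome(sp)
  expect_true(all(tr$mean_h >= 0 & tr$mean_h <= 1))
  # identical predictions for both classes give identical series
  sp_same <- sp
  sp_same$p <- 0.7
  tr2 <- trajectories_by_outcome(sp_same)
  expect_equal(unique(round(tr2$mean_h, 12)), round(binary_entropy(0.7), 12))
})

test_that("the positive class gains confidence across stages on a calibrated cohort", {
  co <- generate_cohort(default_cohort_spec(n = 600, seed = 85))
  folds <- stratified_folds(co$outcome, k = 3, seed = 86)
  sp <- fit_stage_models(co, stage_definitions(), quick_config(seed = 87, n_trees = 60),
                         folds)
  tr <- trajectories_by_outcome(sp)
  pos <- tr$mean_h[tr$outcome == 1]
  expect_lt(pos[5], prior_entropy(co$outcome)$h0)
})

test_that("the cascade resolves the hand-traced four-patient toy correctly", {
  p_by_stage <- rbind(
    c(0.95, 0.95, 0.95, 0.95, 0.95),  # resolves high at stage 1
    c(0.10, 0.50, 0.50, 0.50, 0.50),  # resolves low at stage 1
    c(0.50, 0.92, 0.50, 0.50, 0.50),  # resolves high at stage 2
    c(0.50, 0.50, 0.50, 0.50, 0.50)   # never resolves
  )
  sp <- purrr::map_dfr(1:5, function(s) {
    tibble::tibble(stage = s, label = paste0("s", s), n_features = s,
                   patient_id = 1:4, fold = 1L, p = p_by_stage[, s],
                   outcome = c(1, 0, 1, 1))
  })
  casc <- sequential_resolution(sp, tau_high = 0.90, tau_low = 0.20)
  expect_equal(casc$patients$resolution_stage, c(1L, 1L, 2L, NA))
  expect_equal(casc$patients$arm, c("high", "low", "high", "none"))
  expect_equal(casc$by_stage$cum_resolved, c(2, 3, 3, 3, 3))
  # the resolved classification is frozen: later drifting p is ignored
  summ <- cascade_summary(casc)
  expect_equal(summ$n, c(2L, 1L, 1L))
  expect_equal(sum(summ$n), 4)
})

test_that("boundary probabilities do not resolve under strict thresholds", {
  sp <- purrr::map_dfr(1:2, function(s) {
    tibble::tibble(stage = s, label = paste0("s", s), n_features = s,
                   patient_id = 1:3, fold = 1L,
                   p = c(0.90, 0.20, 0.5), outcome = c(1, 0, 1))
  })
  casc <- sequential_resolution(sp, 0.90, 0.20)
  expect_equal(casc$patients$arm, rep("none", 3))
})

test_that("cascade conservation and threshold monotonicity hold on random fixtures", {
  for (seed in 1:6) {
    sp <- random_stage_preds(200, seed = seed)
    casc <- sequential_resolution(sp, 0.9, 0.2)
    bs <- casc$by_stage
    # conservation: resolved + unresolved = n at every stage
    expect_equal(bs$cum_resolved + bs$unresolved_n, rep(200, 5))
    expect_equal(bs$rule_in_n + bs$low_n, bs$cum_resolved)
    expect_true(all(diff(bs$cum_resolved) >= 0))
    # widening the corridor inward never resolves fewer patients
    wide <- sequential_resolution(sp, 0.85, 0.30)
    expect_true(all(wide$by_stage$cum_resolved >= bs$cum_resolved))
    # permissive thresholds resolve a superset at each stage
    narrow_ids <- casc$patients$patient_id[!is.na(casc$patients$resolution_stage)]
    wide_ids <- wide$patients$patient_id[!is.na(wide$patients$resolution_stage)]
    expect_true(all(narrow_ids %in% wide_ids))
  }
})

test_that("stage-1 gains ignore later stages and patient sets must match", {
  sp <- random_stage_preds(150, seed = 9)
  g1 <- stage_entropy_summary(sp)$marginal_dh_pct[1]
  sp_shuffled <- sp
  sp_shuffled$p[sp_shuffled$stage > 1] <- rev(sp_shuffled$p[sp_shuffled$stage > 1])
  expect_equal(stage_entropy_summary(sp_shuffled)$marginal_dh_pct[1], g1)

  sp_bad <- sp[!(sp$stage == 3 & sp$patient_id == 5), ]
  expect_error(sequential_resolution(sp_bad), "differ",
               class = "uroxai_validation_error")
})

test_that("degenerate cascades behave as expected", {
  sp <- purrr::map_dfr(1:5, function(s) {
    tibble::tibble(stage = s, label = paste0("s", s), n_features = s,
                   patient_id = 1:50, fold = 1L, p = 0.95,
                   outcome = rbinom(50, 1, 0.9))
  })
  casc <- sequential_resolution(sp)
  expect_equal(casc$by_stage$cum_fraction[1], 1)
  expect_true(all(casc$patients$resolution_stage == 1))

  sp2 <- dplyr::mutate(sp, p = 0.5)
  casc2 <- sequential_resolution(sp2)
  expect_equal(casc2$by_stage$cum_resolved[5], 0)
  expect_equal(casc2$by_stage$unresolved_prevalence[5],
               mean(sp2$outcome[sp2$stage == 1]))
})
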