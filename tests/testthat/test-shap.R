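# Interventional attribution: oracle equivalence, additivity, null player,
# dependence curves, stratified tables, subgroup summaries, waterfalls.

test_that("background sampling is unique, seeded, and bounded", {
  co <- generate_cohort(toy_spec(n = 120, seed = 1))
  bg <- sample_background(co, m = 120, seed = 2)
  expect_setequal(bg$indices, seq_len(120))
  bg2 <- sample_background(co, m = 30, seed = 3)
  expect_equal(length(unique(bg2$indices)), 30)
  expect_identical(sample_background(co, 30, seed = 3)$indices, bg2$indices)
  expect_error(sample_background(co, m = 121, seed = 1),
               "exceeds", class = "uroxai_validation_error")
})

test_that("additive predictors have closed-form contributions and zero gap", {
  co <- generate_cohort(toy_spec(n = 60, seed = 4))
  pred <- additive_predictor(0.2, c(x1 = 0.3))
  # fixed background with known mean of x1
  bg <- sample_background(co, m = 20, seed = 5)
  at <- interventional_contributions(pred, co, bg, features = c("x1", "x2"))
  expect_equal(at$x1, 0.3 * (co$x1 - mean(bg$data$x1)), tolerance = 1e-12)
  expect_equal(at$x2, rep(0, 60))  # null player
  re <- reconstruction_error(at)
  expect_lt(re$mean_abs_gap, 1e-12)

  # the worked closed form: f = 0.2 + 0.3 x1, background mean 0.5, x1 = 0.9
  co2 <- tibble::tibble(patient_id = 1:2, x1 = c(0.9, 0.1))
  bg2 <- structure(list(indices = 1:2,
                        data = tibble::tibble(patient_id = 1:2, x1 = c(0.4, 0.6)),
                        m = 2L, seed = 1L), class = "uro_background")
  at2 <- interventional_contributions(pred, co2, bg2, features = "x1")
  expect_equal(at2$x1[1], 0.12, tolerance = 1e-12)
})

test_that("production attribution equals the naive loop oracle exactly", {
  for (seed in 1:3) {
    spec <- toy_spec(n = 40, seed = seed)
    co <- generate_cohort(spec)
    m <- fit_tree_ensemble(co, c("x1", "x2", "x3"), quick_config(seed = seed))
    bg <- sample_background(co, m = 15, seed = seed + 10)
    at <- interventional_contributions(m, co, bg)
    oracle <- naive_interventional(m, co, bg, c("x1", "x2", "x3"))
    expect_lt(max(abs(as.matrix(at[, c("x1", "x2", "x3")]) - oracle$phi)), 1e-12)
    expect_lt(max(abs(at$.pred - oracle$p)), 1e-12)
    expect_equal(at$.base[1], oracle$base, tolerance = 1e-12)
  }
})

test_that("contributions live on the probability scale for probabilistic models", {
  co <- generate_cohort(toy_spec(n = 80, seed = 21))
  m <- fit_tree_ensemble(co, c("x1", "x2", "x3"), quick_config(seed = 22))
  bg <- sample_background(co, 25, seed = 23)
  at <- interventional_contributions(m, co, bg)
  expect_true(all(abs(as.matrix(at[, c("x1", "x2", "x3")])) <= 1))
  # interacting predictor: gap strictly positive but bounded
  pred <- interacting_predictor(c("x1", "x2"))
  at2 <- interventional_contributions(pred, co, bg, features = c("x1", "x2"))
  re <- reconstruction_error(at2)
  expect_gt(re$mean_abs_gap, 0)
  expect_lt(re$mean_abs_gap, 1)
})

test_that("rolling-mean zero crossings interpolate linearly", {
  expect_equal(zero_crossings(c(1, 2, 3, 4), c(-1, -0.5, 0.5, 1)), 2.5)
  expect_equal(zero_crossings(c(1, 2, 3), c(1, 0.5, 0.2)), numeric(0))
  expect_equal(zero_crossings(c(0, 1, 2), c(-1, 1, -1)), c(0.5, 1.5))
})

test_that("dependence curves smooth, detect crossings, and reject constants", {
  co <- generate_cohort(toy_spec(n = 400, seed = 31))
  pred <- additive_predictor(0.5, c(x1 = 0.4))
  bg <- sample_background(co, 50, seed = 32)
  at <- interventional_contributions(pred, co, bg, features = c("x1", "x2"))
  dc <- dependence_curve(at, co, "x1")
  expect_equal(attr(dc, "window"), max(15, ceiling(0.05 * 400)))
  # additive linear effect crosses zero at the background mean of x1
  cr <- attr(dc, "crossings")
  expect_length(cr, 1)
  expect_lt(abs(cr - mean(bg$data$x1)), 0.15)
  # strictly positive contributions give no crossings
  at_pos <- at
  at_pos$x1 <- abs(at$x1) + 0.01
  expect_length(attr(dependence_curve(at_pos, co, "x1"), "crossings"), 0)
  co$flat <- 1
  at$flat <- 0
  expect_error(dependence_curve(at, co, "flat"),
               "constant", class = "uroxai_degenerate_error")
})

test_that("stratified contribution tables conserve counts and recover signs", {
  spec <- cohort_spec(
    3000, 0.5, 41,
    features = list(feat_norm("crp", "blood", 0.5, 1, 0.5, 1, support = c(-10, 20)),
                    feat_norm("other", "history", 0, 1, 0, 1)),
    planted_effects = list(
      planted_effect("crp", "negative_above", magnitude = 2, at = 3)))
  co <- generate_cohort(spec, mode = "causal")
  m <- fit_tree_ensemble(co, c("crp", "other"), quick_config(seed = 42, n_trees = 120))
  bg <- sample_background(co, 60, seed = 43)
  at <- interventional_contributions(m, co, bg)
  tab <- stratified_contribution_table(at, co, "crp", c(-10, 0, 3, 20))
  expect_equal(sum(tab$n), 3000)
  expect_lt(tab$mean_phi[tab$lo == 3], 0)  # above the planted cut: negative
  one <- stratified_contribution_table(at, co, "crp", c(-10, 20))
  expect_equal(one$n, 3000)
  expect_equal(one$mean_phi, mean(at$crp), tolerance = 1e-12)
})

test_that("subgroup summaries partition the cohort and flag degeneracy", {
  co <- generate_cohort(toy_spec(n = 2000, seed = 51))
  pred <- additive_predictor(0.5, c(x1 = 0.1, x2 = 0.1))
  bg <- sample_background(co, 50, seed = 52)
  at <- interventional_contributions(pred, co, bg, features = c("x1", "x2"))
  s <- subgroup_contribution_summary(at, co, "x1", 0, "x2", 0)
  expect_equal(sum(s$subgroups$n), 2000)
  # independent features: rank correlation near zero
  expect_lt(abs(s$spearman_values), 0.05)
  co$const <- 1
  at$const <- 0
  s2 <- subgroup_contribution_summary(at, co, "x1", 0, "const", 0)
  expect_true(s2$degenerate)
  expect_true(is.na(s2$spearman_values))
})

test_that("global ranking is stable across background sizes on a one-signal cohort", {
  set.seed(61)
  n <- 500
  co <- tibble::tibble(patient_id = seq_len(n), s = rnorm(n), u = rnorm(n))
  co$outcome <- rbinom(n, 1, plogis(3 * co$s))
  m <- fit_tree_ensemble(co, c("s", "u"), quick_config(seed = 62))
  sens <- background_size_sensitivity(m, co, sizes = c(20, 40, 80), seed = 63)
  top <- sens$rankings |>
    dplyr::filter(.data$rank == 1) |>
    dplyr::pull(.data$feature)
  expect_equal(unique(top), "s")
  expect_true(all(sens$agreement$spearman > 0.9))
  sens2 <- background_size_sensitivity(m, co, sizes = c(20, 40, 80), seed = 63)
  expect_identical(sens$rankings, sens2$rankings)
})

test_that("waterfalls order, aggregate, and reconcile exactly", {
  co <- generate_cohort(toy_spec(n = 50, seed = 71))
  m <- fit_tree_ensemble(co, c("x1", "x2", "x3"), quick_config(seed = 72))
  bg <- sample_background(co, 20, seed = 73)
  at <- interventional_contributions(m, co, bg)
  wf <- waterfall(at, 7, co, top_k = 2)
  expect_equal(wf$feature[3], "other")
  fts <- c("x1", "x2", "x3")
  expect_equal(sum(wf$phi), sum(as.matrix(at[at$patient_id == 7, fts])),
               tolerance = 1e-12)
  expect_equal(attr(wf, "reconstructed"), attr(wf, "base") + sum(wf$phi),
               tolerance = 1e-12)
  # top_k beyond the feature count: no "other" bucket
  wf2 <- waterfall(at, 7, co, top_k = 10)
  expect_false("other" %in% wf2$feature)
  expect_equal(sort(abs(wf2$phi), decreasing = TRUE), abs(wf2$phi))

  # conflicting strong signals both surface in the top two
  at_fake <- at
  at_fake$x1[at_fake$patient_id == 3] <- 0.4
  at_fake$x2[at_fake$patient_id == 3] <- -0.35
  at_fake$x3[at_fake$patient_id == 3] <- 0.01
  wf3 <- waterfall(at_fake, 3, co, top_k = 2)
  expect_setequal(wf3$feature[1:2], c("x1", "x2"))
})
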