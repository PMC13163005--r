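# Shared fixtures and independent oracles. Oracles deliberately use the
# most literal formulation available (explicit loops, pair enumeration) so
# they stay independent of the production code paths they check.

quick_config <- function(seed = 1, n_trees = 40, ...) {
  model_config(n_trees = n_trees, seed = seed, ...)
}

feat_norm <- function(name, family = "blood", m1 = 1, s1 = 1, m0 = 0, s0 = 1,
                      support = c(-50, 50)) {
  feature_spec(name, family, "continuous", dist = "normal", support = support,
               stone = list(mean = m1, sd = s1),
               nostone = list(mean = m0, sd = s0))
}

feat_bin <- function(name, family = "history", p1 = 0.5, p0 = 0.5) {
  feature_spec(name, family, "binary",
               stone = list(prob = p1), nostone = list(prob = p0))
}

toy_spec <- function(n = 200, prevalence = 0.5, seed = 1, ...) {
  cohort_spec(n, prevalence, seed, features = list(
    feat_norm("x1", "history", 1, 1, 0, 1),
    feat_norm("x2", "physical", 0, 1, 0, 1),
    feat_bin("x3", "blood", 0.6, 0.3)
  ), ...)
}

# Brute-force AUC: enumerate all positive/negative pairs, half credit ties.
pairwise_auc <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# Naive interventional attribution: one predictor call per perturbed row.
naive_interventional <- function(predictor, cohort, background, features) {
  n <- nrow(cohort)
  m <- nrow(background$data)
  p_obs <- numeric(n)
  for (i in seq_len(n)) {
    p_obs[i] <- predict(predictor, cohort[i, , drop = FALSE])
  }
  phi <- matrix(0, n, length(features), dimnames = list(NULL, features))
  for (i in seq_len(n)) {
    for (j in seq_along(features)) {
      acc <- 0
      for (r in seq_len(m)) {
        x <- cohort[i, , drop = FALSE]
        x[[features[j]]] <- background$data[[features[j]]][r]
        acc <- acc + predict(predictor, x)
      }
      phi[i, j] <- p_obs[i] - acc / m
    }
  }
  list(phi = phi, p = p_obs,
       base = mean(vapply(seq_len(m), function(r) {
         predict(predictor, background$data[r, , drop = FALSE])
       }, numeric(1))))
}

# Paired permutation test for a difference in AUC: under the null the two
# models' scores are exchangeable within each patient.
permutation_delta_auc_p <- function(pa, pb, y, reps = 10000, seed = 1) {
  set.seed(seed)
  obs <- abs(roc_auc(pa, y) - roc_auc(pb, y))
  n <- length(y)
  hits <- 0
  for (r in seq_len(reps)) {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, pb, pa)
    b <- ifelse(swap, pa, pb)
    if (abs(roc_auc(a, y) - roc_auc(b, y)) >= obs - 1e-12) hits <- hits + 1
  }
  hits / reps
}

# Binormal score simulator with known true AUC = pnorm(mu / sqrt(2)).
binormal_preds <- function(n1, n0, mu, seed) {
  set.seed(seed)
  tibble::tibble(p = c(rnorm(n1, mu), rnorm(n0, 0)),
                 outcome = c(rep(1, n1), rep(0, n0)))
}

# A predictor with additive structure and a known closed form, wrapped so
# it dispatches through predict() like a fitted model.
additive_predictor <- function(intercept, slopes) {
  structure(list(intercept = intercept, slopes = slopes,
                 features = names(slopes)),
            class = "test_additive")
}

# An interacting predictor (non-additive) for reconstruction-gap checks.
interacting_predictor <- function(features) {
  structure(list(features = features), class = "test_interacting")
}

# Synthetic stage predictions for cascade tests: per-stage probability
# tables over the same patients, arbitrary trajectories.
random_stage_preds <- function(n, n_stages = 5, seed = 1, prevalence = 0.6) {
  set.seed(seed)
  outcome <- rbinom(n, 1, prevalence)
  purrr::map_dfr(seq_len(n_stages), function(s) {
    tibble::tibble(stage = s, label = paste0("s", s), n_features = s,
                   patient_id = seq_len(n), fold = 1L,
                   p = runif(n), outcome = outcome)
  })
}
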