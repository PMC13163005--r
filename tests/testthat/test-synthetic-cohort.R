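# Synthetic cohort generator: validation, determinism, distributional
# fidelity, causal-mode effect planting, and CSV round-trips.

test_that("specification validation names the offending field", {
  expect_error(
    feature_spec("x", "blood", "continuous", dist = "normal",
                 support = c(0, 1),
                 stone = list(mean = 0, sd = -1),
                 nostone = list(mean = 0, sd = 1)),
    "sd must be > 0", class = "uroxai_validation_error")
  expect_error(
    feature_spec("x", "dipstick", "ordinal",
                 stone = list(probs = c(0.5, 0.6)),
                 nostone = list(probs = c(0.5, 0.5))),
    "sum to 1", class = "uroxai_validation_error")
  expect_error(
    feature_spec("x", "blood", "continuous", dist = "normal",
                 support = c(2, 1),
                 stone = list(mean = 0, sd = 1),
                 nostone = list(mean = 0, sd = 1)),
    "ordered", class = "uroxai_validation_error")
  expect_error(cohort_spec(0, 0.5, 1, list(feat_bin("a"))),
               "positive integer", class = "uroxai_validation_error")
  expect_error(cohort_spec(10, 1.2, 1, list(feat_bin("a"))),
               "probability", class = "uroxai_validation_error")
  expect_error(cohort_spec(10, 0.5, 1, list(feat_bin("a"), feat_bin("a"))),
               "Duplicate", class = "uroxai_validation_error")
  expect_error(
    cohort_spec(10, 0.5, 1, list(feat_norm("x", support = c(0, 1))),
                planted_effects = list(
                  planted_effect("x", "threshold_crossing", 1, at = 5))),
    "outside the feature support", class = "uroxai_validation_error")
  expect_error(generate_cohort(toy_spec(), mode = "causal"),
               "planted_effects", class = "uroxai_validation_error")
})

test_that("generation is seed-deterministic and seed-sensitive", {
  a <- generate_cohort(toy_spec(n = 150, seed = 42))
  b <- generate_cohort(toy_spec(n = 150, seed = 42))
  c <- generate_cohort(toy_spec(n = 150, seed = 43))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c)))
})

test_that("outcome prevalence matches the spec within binomial noise", {
  co <- generate_cohort(default_cohort_spec(n = 1000, seed = 7))
  expect_equal(ncol(co), 19)  # id + 17 features + outcome
  expect_lt(abs(mean(co$outcome) - 0.85), 3 * sqrt(0.85 * 0.15 / 1000))
  expect_false(anyNA(co))
})

test_that("degenerate all-constant features give identical rows", {
  spec <- cohort_spec(10, 0.5, 3, features = list(
    feat_bin("a", p1 = 1, p0 = 1), feat_bin("b", p1 = 0, p0 = 0)))
  co <- generate_cohort(spec)
  expect_true(all(co$a == 1))
  expect_true(all(co$b == 0))
  expect_true(all(co$outcome %in% c(0, 1)))
})

test_that("class-conditional marginals match their specification at n = 50,000", {
  spec <- default_cohort_spec(n = 50000, seed = 101)
  co <- generate_cohort(spec)
  for (fs in spec$features) {
    for (cls in c(1, 0)) {
      par <- if (cls == 1) fs$stone else fs$nostone
      x <- co[[fs$name]][co$outcome == cls]
      nn <- length(x)
      if (fs$kind == "continuous" && fs$dist == "normal") {
        mom <- uroxai:::truncnorm_moments(par$mean, par$sd,
                                          fs$support[1], fs$support[2])
        expect_lt(abs(mean(x) - mom$mean), 3 * mom$sd / sqrt(nn),
                  label = paste(fs$name, "mean, class", cls))
        expect_lt(abs(sd(x) - mom$sd), 3 * mom$sd / sqrt(2 * nn),
                  label = paste(fs$name, "sd, class", cls))
      } else if (fs$kind == "continuous" && fs$dist == "lognormal") {
        lp <- uroxai:::lognormal_from_quartiles(par$median, par$q25, par$q75)
        med_se <- 1.2533 * lp$sdlog / sqrt(nn)
        obs <- if (fs$round) stats::median(log(pmax(x, 0.5))) else stats::median(log(x))
        tol <- 3 * med_se + if (fs$round) 0.35 else 0
        expect_lt(abs(obs - lp$meanlog), tol,
                  label = paste(fs$name, "log-median, class", cls))
      } else if (fs$kind == "binary") {
        se <- sqrt(max(par$prob * (1 - par$prob), 1e-6) / nn)
        expect_lt(abs(mean(x) - par$prob), 3 * se + 1e-9,
                  label = paste(fs$name, "rate, class", cls))
      } else if (fs$kind == "ordinal") {
        for (g in seq_along(par$probs)) {
          pg <- par$probs[g]
          se <- sqrt(max(pg * (1 - pg), 1e-6) / nn)
          expect_lt(abs(mean(x == g - 1) - pg), 3 * se + 1e-9,
                    label = paste(fs$name, "grade", g - 1, "class", cls))
        }
      } else if (fs$kind == "zero_inflated") {
        se <- sqrt(par$p_zero * (1 - par$p_zero) / nn)
        expect_lt(abs(mean(x == 0) - par$p_zero), 3 * se,
                  label = paste(fs$name, "zero mass, class", cls))
      }
    }
  }
})

test_that("causal mode plants a recoverable negative_above effect", {
  spec <- cohort_spec(
    20000, 0.5, 11,
    features = list(feat_norm("creatinine", "blood", 1.0, 0.3, 0.9, 0.3,
                              support = c(0.2, 3.5)),
                    feat_norm("noise", "history", 0, 1, 0, 1)),
    planted_effects = list(
      planted_effect("creatinine", "negative_above", magnitude = 1.5, at = 1.0)))
  co <- generate_cohort(spec, mode = "causal")
  above <- co$outcome[co$creatinine > 1.0]
  below <- co$outcome[co$creatinine <= 1.0]
  expect_lt(mean(above), mean(below))
  # realized prevalence stays controlled by the solved intercept
  expect_lt(abs(mean(co$outcome) - 0.5), 3 * sqrt(0.25 / 20000) + 0.005)
})

test_that("a planted threshold crossing moves the outcome log-odds sign near the cut", {
  skip_if_not_installed("mgcv")
  spec <- cohort_spec(
    5000, 0.5, 13,
    features = list(feat_norm("creatinine", "blood", 1.0, 0.3, 0.9, 0.3,
                              support = c(0.2, 3.5))),
    planted_effects = list(
      planted_effect("creatinine", "threshold_crossing", magnitude = 2,
                     at = 0.90)))
  co <- generate_cohort(spec, mode = "causal")
  # independent oracle: monotone-ish smoother of outcome on the feature,
  # sign change of the smoothed log-odds located on a fine grid
  fit <- mgcv::gam(outcome ~ s(creatinine), family = binomial(), data = co)
  grid <- data.frame(creatinine = seq(0.5, 1.5, by = 0.001))
  pr <- predict(fit, grid, type = "response")
  cross <- grid$creatinine[which.min(abs(pr - 0.5))]
  expect_lt(abs(cross - 0.90), 0.05)
})

test_that("cohort CSV round-trips cell-for-cell and rejects bad schemas", {
  co <- generate_cohort(default_cohort_spec(n = 30, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)

  # missing outcome column
  broken <- co[, setdiff(names(co), "outcome")]
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, p2)
  expect_error(read_cohort(p2), "outcome", class = "uroxai_schema_error")

  # one empty cell, named by row and column
  txt <- readr::read_lines(path)
  txt[3] <- sub("^([^,]*),[^,]*", "\\1,", txt[3])
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_lines(txt, p3)
  expect_error(read_cohort(p3), "row 2.*`age`", class = "uroxai_schema_error")

  # non-numeric cell
  txt2 <- readr::read_lines(path)
  txt2[4] <- sub("^([^,]*),[^,]*", "\\1,abc", txt2[4])
  p4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_lines(txt2, p4)
  expect_error(read_cohort(p4), class = "uroxai_schema_error")

  # extra column
  extra <- co
  extra$bogus <- 1
  p5 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(extra, p5)
  expect_error(read_cohort(p5), "bogus", class = "uroxai_schema_error")
})
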