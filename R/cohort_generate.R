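# Synthetic cohort generation and cohort file I/O.

sample_feature_class <- function(fs, n, params) {
  if (n == 0) return(numeric(0))
  x <- switch(
    fs$kind,
    continuous = {
      if (fs$dist == "normal") {
        rtruncnorm(n, params$mean, params$sd, fs$support[1], fs$support[2])
      } else {
        lp <- lognormal_from_quartiles(params$median, params$q25, params$q75)
        pmin(pmax(rlnorm(n, lp$meanlog, lp$sdlog), fs$support[1]), fs$support[2])
      }
    },
    binary = rbinom(n, 1, params$prob),
    ordinal = sample(seq_along(params$probs) - 1L, n, replace = TRUE,
                     prob = params$probs),
    zero_inflated = {
      lp <- lognormal_from_quartiles(params$median, params$q25, params$q75)
      nz <- pmax(1, round(rlnorm(n, lp$meanlog, lp$sdlog)))
      nz <- pmin(nz, fs$support[2])
      ifelse(runif(n) < params$p_zero, 0, nz)
    }
  )
  if (fs$round) x <- round(x)
  as.numeric(x)
}

planted_log_odds <- function(pe, x) {
  switch(pe$shape,
    threshold_crossing = pe$magnitude * as.numeric(x > pe$at),
    window_peak = pe$magnitude * as.numeric(x >= pe$lo & x <= pe$hi),
    negative_above = -pe$magnitude * as.numeric(x > pe$at)
  )
}

#' Generate a seeded synthetic cohort
#'
#' Two generation modes are supported. `class_conditional` draws the outcome
#' first (`Bernoulli(prevalence)`) and then each feature from its
#' class-conditional distribution, reproducing the marginal summaries the
#' specification encodes; features are independent within class. `causal`
#' draws features from the pooled marginals, forms a log-odds risk from an
#' optional linear part plus the planted non-linear effects, solves the
#' intercept numerically so the expected prevalence equals
#' `spec$prevalence`, and draws the outcome from the resulting probability —
#' this mode plants recoverable ground-truth effect shapes.
#'
#' Cohorts are bit-identical for identical specs (including seed).
#'
#' @param spec A [cohort_spec()].
#' @param mode `"class_conditional"` (default) or `"causal"`.
#' @return A tibble with `patient_id`, one column per feature, and a 0/1
#'   `outcome` column; no missing cells.
#' @export
#' @examples
#' spec <- default_cohort_spec(n = 100, seed = 7)
#' cohort <- generate_cohort(spec)
#' mean(cohort$outcome)
generate_cohort <- function(spec, mode = c("class_conditional", "causal")) {
  mode <- match.arg(mode)
  if (!inherits(spec, "cohort_spec")) {
    abort_uroxai("`spec` must be a cohort_spec.", "uroxai_validation_error")
  }
  if (mode == "causal" &&
      (is.null(spec$planted_effects) || length(spec$planted_effects) == 0) &&
      is.null(spec$linear_weights)) {
    abort_uroxai(
      "Causal mode needs planted_effects (or linear_weights) in the spec.",
      "uroxai_validation_error")
  }
  set.seed(spec$seed)
  n <- spec$n
  nm <- spec_feature_names(spec)

  if (mode == "class_conditional") {
    outcome <- rbinom(n, 1, spec$prevalence)
    cols <- lapply(spec$features, function(fs) {
      x <- numeric(n)
      idx1 <- which(outcome == 1)
      idx0 <- which(outcome == 0)
      x[idx1] <- sample_feature_class(fs, length(idx1), fs$stone)
      x[idx0] <- sample_feature_class(fs, length(idx0), fs$nostone)
      x
    })
  } else {
    # Pooled marginal: mixture of the two class-conditional laws.
    cols <- lapply(spec$features, function(fs) {
      from_stone <- runif(n) < spec$prevalence
      x <- numeric(n)
      x[from_stone] <- sample_feature_class(fs, sum(from_stone), fs$stone)
      x[!from_stone] <- sample_feature_class(fs, sum(!from_stone), fs$nostone)
      x
    })
    names(cols) <- nm
    risk <- numeric(n)
    if (!is.null(spec$linear_weights)) {
      for (f in names(spec$linear_weights)) {
        x <- cols[[f]]
        s <- sd(x)
        if (s > 0) risk <- risk + spec$linear_weights[[f]] * (x - mean(x)) / s
      }
    }
    for (pe in spec$planted_effects %||% list()) {
      risk <- risk + planted_log_odds(pe, cols[[pe$feature]])
    }
    # Intercept so that the expected prevalence matches the spec.
    a <- uniroot(function(a) mean(plogis(a + risk)) - spec$prevalence,
                 c(-30, 30), tol = 1e-10)$root
    outcome <- rbinom(n, 1, plogis(a + risk))
  }

  names(cols) <- nm
  out <- tibble::as_tibble(cols)
  out <- dplyr::bind_cols(tibble::tibble(patient_id = seq_len(n)), out)
  out$outcome <- as.numeric(outcome)
  out
}

#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Read and write cohort CSV files
#'
#' The cohort file is UTF-8 comma-separated with a header row: `patient_id`,
#' the 17 feature columns, and a 0/1 `outcome` column. Reading performs a
#' strict schema check (missing/extra columns, non-numeric cells, missing
#' values all raise errors naming the offending columns) so that a
#' round-trip reproduces the table cell-for-cell.
#'
#' @param cohort A cohort tibble as produced by [generate_cohort()].
#' @param path File path.
#' @param feature_names Expected feature columns; defaults to the shipped
#'   17-feature configuration.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()`
#'   returns `path` invisibly.
#' @name cohort_io
#' @export
read_cohort <- function(path, feature_names = NULL) {
  if (is.null(feature_names)) {
    feature_names <- spec_feature_names(default_cohort_spec())
  }
  raw <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(.default = readr::col_double())))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort_uroxai(
      sprintf("Non-numeric cells in cohort file (first at row %d, column %d).",
              prob$row[1], prob$col[1]),
      "uroxai_schema_error")
  }
  expected <- c("patient_id", feature_names, "outcome")
  missing_cols <- setdiff(expected, names(raw))
  extra_cols <- setdiff(names(raw), expected)
  if (length(missing_cols) > 0 || length(extra_cols) > 0) {
    abort_uroxai(
      paste0("Cohort schema mismatch.",
             if (length(missing_cols)) paste0(" Missing: ", paste(missing_cols, collapse = ", "), "."),
             if (length(extra_cols)) paste0(" Unexpected: ", paste(extra_cols, collapse = ", "), ".")),
      "uroxai_schema_error")
  }
  raw <- raw[, expected]
  if (anyNA(raw)) {
    idx <- which(is.na(as.matrix(raw)), arr.ind = TRUE)[1, ]
    abort_uroxai(
      sprintf("Missing value at row %d, column `%s`.", idx[1], names(raw)[idx[2]]),
      "uroxai_schema_error")
  }
  validate_cohort(raw, feature_names)
  raw
}

# Structural checks shared by the generator output and file reader.
validate_cohort <- function(cohort, feature_names = NULL) {
  if (!is.data.frame(cohort)) {
    abort_uroxai("Cohort must be a data frame.", "uroxai_schema_error")
  }
  need <- c("patient_id", "outcome")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    abort_uroxai(paste0("Cohort lacks column(s): ", paste(miss, collapse = ", "), "."),
                 "uroxai_schema_error")
  }
  if (anyNA(cohort)) {
    abort_uroxai("Cohort contains missing cells; complete cases are required.",
                 "uroxai_schema_error")
  }
  check_binary_outcome(cohort$outcome)
  invisible(cohort)
}
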