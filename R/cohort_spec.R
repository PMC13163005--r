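#' Specify one synthetic cohort feature
#'
#' A feature is described by its family in the emergency-department workup
#' (history, physical exam, dipstick, microscopy, blood), its measurement
#' kind, and class-conditional distribution parameters for the stone and
#' no-stone groups.
#'
#' Supported kinds and their parameter lists:
#' * `continuous` with `dist = "normal"`: `mean`, `sd` (sampled as a normal
#'   truncated to `support`).
#' * `continuous` with `dist = "lognormal"`: `median`, `q25`, `q75`
#'   (converted to `meanlog`/`sdlog`; clipped to `support`).
#' * `binary`: `prob`, the event probability.
#' * `ordinal`: `probs`, category probabilities for integer grades
#'   `0 .. length(probs) - 1`.
#' * `zero_inflated`: `p_zero` plus `median`/`q25`/`q75` of the non-zero
#'   part (rounded lognormal, floored at 1); used for near-degenerate counts
#'   such as urine WBC.
#'
#' @param name Feature name (column name in the cohort table).
#' @param family One of `"history"`, `"physical"`, `"dipstick"`,
#'   `"microscopy"`, `"blood"`.
#' @param kind One of `"continuous"`, `"binary"`, `"ordinal"`,
#'   `"zero_inflated"`.
#' @param stone,nostone Named lists of class-conditional parameters (see
#'   Details).
#' @param dist For continuous features, `"normal"` or `"lognormal"`.
#' @param support Numeric length-2 closed interval for continuous /
#'   zero-inflated features.
#' @param round Logical; round sampled values to integers (counts).
#' @return An object of class `"feature_spec"`.
#' @export
feature_spec <- function(name, family, kind, stone, nostone,
                         dist = NULL, support = NULL, round = FALSE) {
  fs <- structure(
    list(name = name, family = family, kind = kind, dist = dist,
         support = support, round = isTRUE(round),
         stone = stone, nostone = nostone),
    class = "feature_spec"
  )
  validate_feature_spec(fs)
  fs
}

validate_feature_spec <- function(fs) {
  bad <- function(field, msg) {
    abort_uroxai(sprintf("Feature `%s`: invalid `%s` — %s", fs$name, field, msg),
                 "uroxai_validation_error")
  }
  if (!is.character(fs$name) || length(fs$name) != 1 || !nzchar(fs$name)) {
    abort_uroxai("Feature name must be a non-empty string.",
                 "uroxai_validation_error")
  }
  families <- c("history", "physical", "dipstick", "microscopy", "blood")
  if (!fs$family %in% families) bad("family", paste("must be one of", paste(families, collapse = ", ")))
  kinds <- c("continuous", "binary", "ordinal", "zero_inflated")
  if (!fs$kind %in% kinds) bad("kind", paste("must be one of", paste(kinds, collapse = ", ")))
  if (!is.null(fs$support)) {
    if (length(fs$support) != 2 || !is.numeric(fs$support) || fs$support[1] >= fs$support[2]) {
      bad("support", "bounds must be numeric and ordered lo < hi")
    }
  }
  for (cls in c("stone", "nostone")) {
    p <- fs[[cls]]
    if (fs$kind == "continuous") {
      if (is.null(fs$dist) || !fs$dist %in% c("normal", "lognormal")) {
        bad("dist", "continuous features need dist normal or lognormal")
      }
      if (is.null(fs$support)) bad("support", "continuous features need a support interval")
      if (fs$dist == "normal") {
        if (is.null(p$mean) || is.null(p$sd)) bad(cls, "normal needs mean and sd")
        if (p$sd <= 0) bad(cls, "sd must be > 0")
      } else {
        if (any(vapply(c("median", "q25", "q75"), function(k) is.null(p[[k]]), TRUE))) {
          bad(cls, "lognormal needs median, q25, q75")
        }
        if (!(p$q25 < p$median && p$median < p$q75) && !(p$q25 < p$q75)) {
          bad(cls, "quartiles must be ordered q25 < q75")
        }
        if (p$q25 <= 0) bad(cls, "lognormal quartiles must be positive")
      }
    } else if (fs$kind == "binary") {
      if (is.null(p$prob) || p$prob < 0 || p$prob > 1) bad(cls, "prob must lie in [0, 1]")
    } else if (fs$kind == "ordinal") {
      if (is.null(p$probs) || any(p$probs < 0) ||
          abs(sum(p$probs) - 1) > 1e-9) {
        bad(cls, "probs must be non-negative and sum to 1 (tol 1e-9)")
      }
    } else { # zero_inflated
      if (is.null(p$p_zero) || p$p_zero < 0 || p$p_zero > 1) bad(cls, "p_zero must lie in [0, 1]")
      if (any(vapply(c("median", "q25", "q75"), function(k) is.null(p[[k]]), TRUE))) {
        bad(cls, "zero_inflated needs median, q25, q75 of the non-zero part")
      }
    }
  }
  invisible(fs)
}

#' Specify a planted non-linear effect for causal-mode generation
#'
#' Planted effects let the generator embed known non-linearities — of the
#' shapes reported for creatinine (sign change at a threshold), pain duration
#' (peak window) and CRP (negative signal above a cut) — so that recovery of
#' those shapes by the attribution machinery can be tested.
#'
#' @param feature Feature name the effect acts on.
#' @param shape One of `"threshold_crossing"` (adds `magnitude` to the
#'   log-odds above `at`), `"window_peak"` (adds `magnitude` inside
#'   `[lo, hi]`), `"negative_above"` (subtracts `magnitude` above `at`).
#' @param magnitude Effect size in log-odds units (> 0).
#' @param at Threshold for `threshold_crossing` / `negative_above`.
#' @param lo,hi Window bounds for `window_peak`.
#' @return An object of class `"planted_effect"`.
#' @export
planted_effect <- function(feature,
                           shape = c("threshold_crossing", "window_peak", "negative_above"),
                           magnitude, at = NULL, lo = NULL, hi = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(magnitude) || magnitude <= 0) {
    abort_uroxai("`magnitude` must be a positive log-odds value.",
                 "uroxai_validation_error")
  }
  if (shape %in% c("threshold_crossing", "negative_above") && is.null(at)) {
    abort_uroxai(sprintf("Shape `%s` needs `at`.", shape), "uroxai_validation_error")
  }
  if (shape == "window_peak" && (is.null(lo) || is.null(hi) || lo >= hi)) {
    abort_uroxai("Shape `window_peak` needs ordered `lo < hi`.",
                 "uroxai_validation_error")
  }
  structure(list(feature = feature, shape = shape, magnitude = magnitude,
                 at = at, lo = lo, hi = hi),
            class = "planted_effect")
}

#' Build a full cohort specification
#'
#' @param n Number of patients (>= 1).
#' @param prevalence Outcome prevalence in (0, 1); defaults to the 0.85 of
#'   the CT-referred study population.
#' @param seed Integer seed; cohorts are bit-identical for equal seeds.
#' @param features List of [feature_spec()] objects (17 in the default
#'   configuration).
#' @param planted_effects Optional list of [planted_effect()] objects, used
#'   only by causal-mode generation.
#' @param linear_weights Optional named numeric vector of per-SD log-odds
#'   weights for the linear part of the causal-mode risk.
#' @return An object of class `"cohort_spec"`.
#' @seealso [default_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n, prevalence = 0.85, seed = 1L, features,
                        planted_effects = NULL, linear_weights = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort_uroxai("`n` must be a positive integer.", "uroxai_validation_error")
  }
  check_prob(prevalence, "prevalence", open = TRUE)
  if (!is.numeric(seed) || length(seed) != 1) {
    abort_uroxai("`seed` must be a single integer.", "uroxai_validation_error")
  }
  if (!is.list(features) || length(features) == 0) {
    abort_uroxai("`features` must be a non-empty list of feature_spec objects.",
                 "uroxai_validation_error")
  }
  for (fs in features) {
    if (!inherits(fs, "feature_spec")) {
      abort_uroxai("Every element of `features` must be a feature_spec.",
                   "uroxai_validation_error")
    }
  }
  nm <- vapply(features, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    abort_uroxai(sprintf("Duplicate feature names: %s.",
                         paste(unique(nm[duplicated(nm)]), collapse = ", ")),
                 "uroxai_validation_error")
  }
  if (!is.null(planted_effects)) {
    for (pe in planted_effects) {
      if (!inherits(pe, "planted_effect")) {
        abort_uroxai("`planted_effects` must be planted_effect objects.",
                     "uroxai_validation_error")
      }
      if (!pe$feature %in% nm) {
        abort_uroxai(sprintf("Planted effect targets unknown feature `%s`.", pe$feature),
                     "uroxai_validation_error")
      }
      fs <- features[[match(pe$feature, nm)]]
      if (!is.null(fs$support)) {
        pts <- c(pe$at, pe$lo, pe$hi)
        if (any(pts < fs$support[1] | pts > fs$support[2])) {
          abort_uroxai(sprintf(
            "Planted effect on `%s`: breakpoints outside the feature support.",
            pe$feature), "uroxai_validation_error")
        }
      }
    }
  }
  if (!is.null(linear_weights)) {
    if (is.null(names(linear_weights)) || !all(names(linear_weights) %in% nm)) {
      abort_uroxai("`linear_weights` must be named after known features.",
                   "uroxai_validation_error")
    }
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 seed = as.integer(seed), features = features,
                 planted_effects = planted_effects,
                 linear_weights = linear_weights),
            class = "cohort_spec")
}

#' The shipped default cohort specification
#'
#' Reads the packaged YAML configuration encoding the class-conditional
#' feature summaries of the 1000-patient CT-referred study population
#' (stone prevalence 85.0%).
#'
#' @param path Optional path to an alternative YAML configuration.
#' @param n,prevalence,seed Optional overrides of the configured values.
#' @return A [cohort_spec()] object with 17 features.
#' @export
#' @examples
#' spec <- default_cohort_spec(n = 200, seed = 1)
#' cohort <- generate_cohort(spec)
default_cohort_spec <- function(path = NULL, n = NULL, prevalence = NULL,
                                seed = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_cohort.yaml", package = "uroxai")
  }
  cfg <- yaml::read_yaml(path)
  features <- lapply(cfg$features, function(f) {
    feature_spec(
      name = f$name, family = f$family, kind = f$kind,
      dist = f$dist,
      support = if (!is.null(f$support)) as.numeric(f$support),
      round = isTRUE(f$round),
      stone = f$stone, nostone = f$nostone
    )
  })
  cohort_spec(
    n = n %||% cfg$n,
    prevalence = prevalence %||% cfg$prevalence,
    seed = seed %||% cfg$seed,
    features = features
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Feature names of a cohort specification
#' @param spec A [cohort_spec()].
#' @return Character vector of feature names in column order.
#' @export
spec_feature_names <- function(spec) {
  vapply(spec$features, `[[`, character(1), "name")
}

#' Feature families as a lookup table
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `feature`, `family`, `kind`.
#' @export
spec_feature_table <- function(spec) {
  tibble::tibble(
    feature = spec_feature_names(spec),
    family = vapply(spec$features, `[[`, character(1), "family"),
    kind = vapply(spec$features, `[[`, character(1), "kind")
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> n = %d, prevalence = %.3f, seed = %d, %d features\n",
              x$n, x$prevalence, x$seed, length(x$features)))
  if (!is.null(x$planted_effects)) {
    cat(sprintf("  planted effects: %d\n", length(x$planted_effects)))
  }
  invisible(x)
}
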