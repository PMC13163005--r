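# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package flows from one root seed. Each randomized
#' step derives its own seed as a deterministic polynomial hash of the root
#' seed and a step label, so that adding or reordering steps never perturbs
#' the seeds of the others. Results stay inside the 32-bit integer range.
#'
#' @param seed Integer root seed.
#' @param label Character step label (e.g. `"folds"`, `"background"`).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(7, "folds")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(label)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

abort_uroxai <- function(message, class, ...) {
  abort(message, class = c(class, "uroxai_error"), ...)
}

# Validate a probability-like scalar.
check_prob <- function(x, name, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) {
    abort_uroxai(
      sprintf("`%s` must be a probability in %s, got %s.",
              name, if (open) "(0, 1)" else "[0, 1]",
              paste(format(x), collapse = ", ")),
      "uroxai_validation_error"
    )
  }
  invisible(x)
}

# Extract (p, outcome) from an out-of-fold prediction table or vector pair.
as_pred_frame <- function(preds, outcome = NULL) {
  if (is.data.frame(preds)) {
    need <- c("p", "outcome")
    miss <- setdiff(need, names(preds))
    if (length(miss) > 0) {
      abort_uroxai(
        paste0("Prediction table lacks column(s): ",
               paste(miss, collapse = ", "), "."),
        "uroxai_validation_error"
      )
    }
    tibble::tibble(p = as.numeric(preds$p), outcome = as.numeric(preds$outcome))
  } else {
    if (is.null(outcome) || length(outcome) != length(preds)) {
      abort_uroxai("Supply `outcome` with the same length as `p`.",
                   "uroxai_validation_error")
    }
    tibble::tibble(p = as.numeric(preds), outcome = as.numeric(outcome))
  }
}

check_binary_outcome <- function(outcome) {
  if (length(outcome) == 0 || anyNA(outcome) || !all(outcome %in% c(0, 1))) {
    abort_uroxai("Outcomes must be 0/1 with no missing values.",
                 "uroxai_validation_error")
  }
  invisible(outcome)
}

# Truncated-normal sampler via inverse-CDF; exact truncation, not clipping.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Closed-form moments of the truncated normal, used by tests as the oracle
# the generator is checked against.
truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- pnorm(b) - pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(v))
}

# Convert a median/IQR summary to lognormal meanlog/sdlog.
lognormal_from_quartiles <- function(median, q25, q75) {
  list(meanlog = log(median),
       sdlog = log(q75 / q25) / (2 * qnorm(0.75)))
}
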