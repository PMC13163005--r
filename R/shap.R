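# Interventional Shapley attribution by background marginalization, and its
# downstream analyses (dependence curves, stratified tables, waterfalls).

#' Draw the background sample for attribution
#'
#' Simple random sampling without replacement from the cohort, with a fixed
#' seed. The background plays the role of the reference distribution the
#' marginalization averages over; its mean prediction is the base value.
#'
#' @param cohort Cohort data frame.
#' @param m Background size (default 100).
#' @param seed Integer seed.
#' @return An object of class `"uro_background"`: list with `indices`,
#'   `data` (the sampled rows), `m`, `seed`.
#' @export
sample_background <- function(cohort, m = 100, seed = 1L) {
  n <- nrow(cohort)
  if (m > n) {
    abort_uroxai(sprintf("Background size m = %d exceeds cohort size %d.", m, n),
                 "uroxai_validation_error")
  }
  if (m < 1) {
    abort_uroxai("`m` must be >= 1.", "uroxai_validation_error")
  }
  set.seed(seed)
  idx <- sample.int(n, m, replace = FALSE)
  structure(list(indices = idx, data = cohort[idx, , drop = FALSE],
                 m = as.integer(m), seed = as.integer(seed)),
            class = "uro_background")
}

#' Interventional per-feature contributions
#'
#' For patient `i` and feature `j`, the contribution is
#' `phi_ij = p_i - mean_r f(x_i with feature j replaced by x_rj)`, the mean
#' change in predicted probability when the feature of interest is replaced
#' by background values while all other features stay at their observed
#' values. This single-feature marginalization is the interventional
#' ("do-calculus") reading; it is not the coalition-averaged exact
#' tree-Shapley computation, and the gap between `sum_j phi_ij` and
#' `p_i - base` is reported by [reconstruction_error()] rather than assumed
#' to vanish. For additive predictors the two coincide and the gap is zero.
#'
#' Contributions are on the probability scale, so `|phi| <= 1` always.
#'
#' @param predictor A fitted model with a `predict(object, newdata)` method
#'   returning probabilities (e.g. [fit_tree_ensemble()] output).
#' @param cohort Data frame of patients to explain.
#' @param background A [sample_background()] object.
#' @param features Features to attribute; defaults to the predictor's
#'   feature list (or all shared columns).
#' @return An object of class `"uro_attr"`: a tibble with `patient_id`,
#'   one `phi` column per feature, and columns `.pred` (model prediction)
#'   and `.base` (mean background prediction).
#' @export
interventional_contributions <- function(predictor, cohort, background,
                                         features = NULL) {
  if (!inherits(background, "uro_background")) {
    abort_uroxai("`background` must come from sample_background().",
                 "uroxai_validation_error")
  }
  if (is.null(features)) {
    features <- predictor$features %||% setdiff(names(cohort), c("patient_id", "outcome"))
  }
  n <- nrow(cohort)
  m <- background$m
  p_obs <- predict(predictor, cohort)
  base <- mean(predict(predictor, background$data))
  phi <- matrix(NA_real_, n, length(features), dimnames = list(NULL, features))
  for (j in seq_along(features)) {
    f <- features[j]
    # All n x m perturbed rows for this feature in one predictor call:
    # patient block i holds x_i with feature f set to each background value.
    rep_idx <- rep(seq_len(n), each = m)
    newdata <- cohort[rep_idx, , drop = FALSE]
    newdata[[f]] <- rep(background$data[[f]], times = n)
    pm <- tryCatch(predict(predictor, newdata), error = function(e) {
      abort_uroxai(sprintf("Predictor failed while marginalizing feature `%s`: %s",
                           f, conditionMessage(e)), "uroxai_predict_error")
    })
    phi[, j] <- p_obs - colMeans(matrix(pm, nrow = m))
  }
  out <- tibble::as_tibble(as.data.frame(phi))
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = cohort$patient_id %||% seq_len(n)), out)
  out$.pred <- p_obs
  out$.base <- base
  class(out) <- c("uro_attr", class(tibble::tibble()))
  out
}

attr_features <- function(attr) {
  setdiff(names(attr), c("patient_id", ".pred", ".base"))
}

#' Attribution reconstruction error
#'
#' The per-patient absolute gap between the sum of contributions and the
#' difference between the patient's prediction and the base value,
#' `|sum_j phi_ij - (p_i - base)|`, plus its cohort mean. The gap is exactly
#' zero for additive predictors; for interacting predictors it quantifies
#' the approximation cost of single-feature marginalization.
#'
#' @param attr An attribution table from [interventional_contributions()].
#' @return A list: `per_patient` (tibble `patient_id`, `gap`) and
#'   `mean_abs_gap`.
#' @export
reconstruction_error <- function(attr) {
  fts <- attr_features(attr)
  s <- rowSums(as.matrix(attr[, fts, drop = FALSE]))
  gap <- abs(s - (attr$.pred - attr$.base))
  list(per_patient = tibble::tibble(patient_id = attr$patient_id, gap = gap),
       mean_abs_gap = mean(gap))
}

#' Locate zero crossings of a piecewise-linear curve
#'
#' Sign changes of `y` between consecutive points are located by linear
#' interpolation on `x`; exact zeros are reported at their own `x`.
#'
#' @param x Increasing abscissae.
#' @param y Curve values.
#' @return Numeric vector of crossing locations (possibly empty), in order.
#' @export
#' @examples
#' zero_crossings(c(1, 2, 3, 4), c(-1, -0.5, 0.5, 1))  # 2.5
zero_crossings <- function(x, y) {
  stopifnot(length(x) == length(y))
  out <- numeric(0)
  for (i in seq_len(length(y) - 1)) {
    y0 <- y[i]; y1 <- y[i + 1]
    if (y0 == 0 && (i == 1 || y[i - 1] != 0)) out <- c(out, x[i])
    if (y0 * y1 < 0) {
      out <- c(out, x[i] + (x[i + 1] - x[i]) * (0 - y0) / (y1 - y0))
    }
  }
  if (length(y) > 1 && y[length(y)] == 0 && y[length(y) - 1] != 0) {
    out <- c(out, x[length(y)])
  }
  out
}

#' Dependence curve of a feature's contribution
#'
#' Sorts patients by feature value, overlays a centered rolling mean of the
#' contributions (window `max(15, ceiling(window_fraction * n))`, shrunk at
#' the edges), and locates the zero crossings of the smoothed trend by
#' linear interpolation. Crossings should be read as transition regions of
#' roughly one window width, not as precise cut-points.
#'
#' @param attr Attribution table.
#' @param cohort The cohort the attributions were computed on (same order).
#' @param feature Feature name.
#' @param window_fraction Rolling-window width as a fraction of `n`.
#' @return An object of class `"uro_depcurve"`: tibble with `value`, `phi`,
#'   `trend`, plus attributes `crossings`, `window`, `feature`.
#' @export
dependence_curve <- function(attr, cohort, feature, window_fraction = 0.05) {
  x <- cohort[[feature]]
  if (is.null(x)) {
    abort_uroxai(sprintf("Feature `%s` absent from cohort.", feature),
                 "uroxai_schema_error")
  }
  if (length(unique(x)) < 2) {
    abort_uroxai(sprintf("Feature `%s` is constant; no dependence curve.", feature),
                 "uroxai_degenerate_error")
  }
  phi <- attr[[feature]]
  if (is.null(phi)) {
    abort_uroxai(sprintf("No attribution column for feature `%s`.", feature),
                 "uroxai_schema_error")
  }
  ord <- order(x)
  xs <- x[ord]
  ps <- phi[ord]
  n <- length(xs)
  w <- max(15, ceiling(window_fraction * n))
  half <- floor(w / 2)
  cs <- cumsum(c(0, ps))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  trend <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  out <- tibble::tibble(value = xs, phi = ps, trend = trend)
  attr(out, "crossings") <- zero_crossings(xs, trend)
  attr(out, "window") <- w
  attr(out, "feature") <- feature
  class(out) <- c("uro_depcurve", class(tibble::tibble()))
  out
}

#' Stratified contributions and outcome prevalence by feature interval
#'
#' Cuts the feature's range at the supplied edges into half-open intervals
#' `[lo, hi)` (last closed) and reports, per interval, the patient count,
#' observed outcome percentage, and the mean and SD of the feature's
#' contribution — the tabular counterpart of a dependence plot.
#'
#' @inheritParams dependence_curve
#' @param edges Increasing interval boundaries covering the values of
#'   interest.
#' @return A tibble: `interval`, `lo`, `hi`, `n`, `stone_pct`, `mean_phi`,
#'   `sd_phi`.
#' @export
stratified_contribution_table <- function(attr, cohort, feature, edges) {
  if (is.unsorted(edges, strictly = TRUE)) {
    abort_uroxai("`edges` must be strictly increasing.", "uroxai_validation_error")
  }
  x <- cohort[[feature]]
  phi <- attr[[feature]]
  y <- cohort$outcome
  k <- length(edges) - 1
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tibble::tibble(
    interval = sprintf("[%g, %g%s", edges[-length(edges)], edges[-1],
                       c(rep(")", k - 1), "]")),
    lo = edges[-length(edges)],
    hi = edges[-1],
    n = vapply(seq_len(k), function(i) sum(idx == i), integer(1)),
    stone_pct = vapply(seq_len(k), function(i) {
      if (any(idx == i)) 100 * mean(y[idx == i]) else NA_real_
    }, numeric(1)),
    mean_phi = vapply(seq_len(k), function(i) {
      if (any(idx == i)) mean(phi[idx == i]) else NA_real_
    }, numeric(1)),
    sd_phi = vapply(seq_len(k), function(i) {
      if (sum(idx == i) > 1) sd(phi[idx == i]) else NA_real_
    }, numeric(1))
  )
}

#' Two-by-two subgroup contribution summary
#'
#' Splits the cohort by a cut on feature A and positivity of feature B and
#' reports, per subgroup, the patient count and the mean contribution of
#' both features; also reports tie-corrected Spearman rank correlations of
#' the two features' raw values and of their contribution columns. Used to
#' check whether the model treats two clinically related markers as
#' substitutes or as distinct signals.
#'
#' @inheritParams dependence_curve
#' @param feature_a,feature_b The two features.
#' @param cut_a Threshold on feature A (subgroups `<= cut_a` vs `> cut_a`).
#' @param cut_b Positivity threshold on feature B (negative `<= cut_b`).
#' @return A list: `subgroups` (tibble with `group_a`, `group_b`, `n`,
#'   `mean_phi_a`, `mean_phi_b`), `spearman_values`, `spearman_phi`
#'   (either may be `NA` with a flag if a feature is constant).
#' @export
subgroup_contribution_summary <- function(attr, cohort, feature_a, cut_a,
                                          feature_b, cut_b = 0) {
  xa <- cohort[[feature_a]]
  xb <- cohort[[feature_b]]
  ga <- factor(ifelse(xa > cut_a, "high", "low"), levels = c("low", "high"))
  gb <- factor(ifelse(xb > cut_b, "positive", "negative"),
               levels = c("negative", "positive"))
  d <- tibble::tibble(group_a = ga, group_b = gb,
                      phi_a = attr[[feature_a]], phi_b = attr[[feature_b]])
  subgroups <- d |>
    dplyr::group_by(.data$group_a, .data$group_b, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_phi_a = if (dplyr::n() > 0) mean(.data$phi_a) else NA_real_,
                     mean_phi_b = if (dplyr::n() > 0) mean(.data$phi_b) else NA_real_,
                     .groups = "drop")
  sp <- function(u, v) {
    if (sd(u) == 0 || sd(v) == 0) return(NA_real_)
    cor(u, v, method = "spearman")
  }
  list(subgroups = subgroups,
       spearman_values = sp(xa, xb),
       spearman_phi = sp(attr[[feature_a]], attr[[feature_b]]),
       degenerate = sd(xa) == 0 || sd(xb) == 0)
}

#' Sensitivity of the global ranking to background size
#'
#' Recomputes attributions at several background sizes and compares the
#' global rankings by mean absolute contribution, reporting pairwise
#' Spearman rank agreement between sizes.
#'
#' @param predictor Fitted model.
#' @param cohort Cohort to explain.
#' @param sizes Background sizes to try.
#' @param seed Root seed; each size derives its own background seed.
#' @param features Features to attribute (default: predictor's features).
#' @return A list: `rankings` (tibble `size`, `feature`, `mean_abs_phi`,
#'   `rank`) and `agreement` (tibble `size_a`, `size_b`, `spearman`).
#' @export
background_size_sensitivity <- function(predictor, cohort,
                                        sizes = c(50, 100, 200), seed = 1L,
                                        features = NULL) {
  rankings <- purrr::map_dfr(sizes, function(m) {
    bg <- sample_background(cohort, m = m,
                            seed = derive_seed(seed, paste0("background", m)))
    at <- interventional_contributions(predictor, cohort, bg, features)
    fts <- attr_features(at)
    mabs <- colMeans(abs(as.matrix(at[, fts, drop = FALSE])))
    tibble::tibble(size = m, feature = fts, mean_abs_phi = mabs,
                   rank = rank(-mabs, ties.method = "average"))
  })
  pairs <- utils::combn(sizes, 2)
  agreement <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    ra <- rankings[rankings$size == pairs[1, i], ]
    rb <- rankings[rankings$size == pairs[2, i], ]
    rb <- rb[match(ra$feature, rb$feature), ]
    tibble::tibble(size_a = pairs[1, i], size_b = pairs[2, i],
                   spearman = cor(ra$mean_abs_phi, rb$mean_abs_phi,
                                  method = "spearman"))
  })
  list(rankings = rankings, agreement = agreement)
}

#' Per-patient waterfall explanation
#'
#' Orders one patient's contributions by absolute magnitude, keeps the top
#' `top_k`, aggregates the remainder into an `"other"` row, and reports the
#' base value, the reconstructed sum `base + sum(phi)` and the model
#' prediction side by side.
#'
#' @param attr Attribution table.
#' @param patient_id Patient identifier (matched against the attribution
#'   table's `patient_id`).
#' @param cohort Optional cohort supplying observed feature values.
#' @param top_k Number of features listed individually.
#' @return An object of class `"uro_waterfall"`: tibble with `feature`,
#'   `value`, `phi`; attributes `base`, `prediction`, `reconstructed`,
#'   `patient_id`.
#' @export
waterfall <- function(attr, patient_id, cohort = NULL, top_k = 10) {
  i <- match(patient_id, attr$patient_id)
  if (is.na(i)) {
    abort_uroxai(sprintf("Patient `%s` not found.", format(patient_id)),
                 "uroxai_validation_error")
  }
  fts <- attr_features(attr)
  phi <- as.numeric(as.matrix(attr[i, fts]))
  names(phi) <- fts
  vals <- if (!is.null(cohort)) {
    j <- match(patient_id, cohort$patient_id)
    as.numeric(as.matrix(cohort[j, fts]))
  } else {
    rep(NA_real_, length(fts))
  }
  ord <- order(-abs(phi))
  keep <- head(ord, top_k)
  rest <- setdiff(ord, keep)
  out <- tibble::tibble(feature = fts[keep], value = vals[keep], phi = phi[keep])
  if (length(rest) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      feature = "other", value = NA_real_, phi = sum(phi[rest])))
  }
  attr(out, "base") <- attr$.base[i]
  attr(out, "prediction") <- attr$.pred[i]
  attr(out, "reconstructed") <- attr$.base[i] + sum(phi)
  attr(out, "patient_id") <- patient_id
  class(out) <- c("uro_waterfall", class(tibble::tibble()))
  out
}
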