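# ggplot2 displays for the main result types.

#' @exportS3Method ggplot2::autoplot
autoplot.uro_calibration <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean_p, y = .data$obs_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability", y = "Observed stone rate",
                  size = "Patients", title = "Quantile calibration") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.uro_depcurve <- function(object, ...) {
  feature <- attr(object, "feature")
  crossings <- attr(object, "crossings")
  g <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$phi), alpha = 0.25, size = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$trend), linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = feature, y = "Contribution to predicted probability",
                  title = sprintf("Dependence of attribution on %s", feature)) +
    ggplot2::theme_minimal()
  if (length(crossings) > 0) {
    g <- g + ggplot2::geom_vline(xintercept = crossings, colour = "orange",
                                 linetype = "dotted")
  }
  g
}

#' @exportS3Method ggplot2::autoplot
autoplot.uro_waterfall <- function(object, ...) {
  d <- dplyr::mutate(object,
                     feature = factor(.data$feature, levels = rev(.data$feature)),
                     direction = ifelse(.data$phi >= 0, "favors stone", "opposes stone"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$phi, y = .data$feature,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::scale_fill_manual(values = c("favors stone" = "#c0392b",
                                          "opposes stone" = "#2980b9")) +
    ggplot2::labs(
      x = "Contribution to predicted probability", y = NULL, fill = NULL,
      title = sprintf("Patient %s: prediction %.3f (base %.3f)",
                      format(attr(object, "patient_id")),
                      attr(object, "prediction"), attr(object, "base"))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.uro_projection <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           cols = c("ppv_high", "npv_low"),
                           names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$prevalence, y = .data$value,
                                  colour = .data$measure)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::scale_colour_manual(
      values = c(ppv_high = "#c0392b", npv_low = "#2980b9"),
      labels = c(ppv_high = "PPV (high arm)", npv_low = "NPV (low arm)")) +
    ggplot2::labs(x = "Baseline prevalence", y = "Predictive value",
                  colour = NULL, title = "Prevalence projection") +
    ggplot2::theme_minimal()
}

#' Stage entropy and discrimination display
#'
#' Bars for mean per-stage entropy with the AUC overlaid, the visual
#' companion of the stage report.
#'
#' @param stagerep A [stage_entropy_summary()] or [stage_report()] tibble.
#' @return A ggplot object.
#' @export
plot_stage_entropy <- function(stagerep) {
  ggplot2::ggplot(stagerep, ggplot2::aes(x = factor(.data$stage))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$mean_h), fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$auc, group = 1),
                       colour = "darkgreen", linewidth = 1) +
    ggplot2::geom_point(ggplot2::aes(y = .data$auc), colour = "darkgreen") +
    ggplot2::labs(x = "Testing stage", y = "Mean entropy (bits) / AUC",
                  title = "Sequential information gain") +
    ggplot2::theme_minimal()
}
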