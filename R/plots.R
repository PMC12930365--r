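#' Bland-Altman plot
#'
#' Per-well replicate differences against replicate means, with the
#' bias and 95% limits of agreement as horizontal lines.
#'
#' @param object A `bland_altman` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
      linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "Mean of replicates (OD600)", y = "Difference between replicates (OD600)",
      title = sprintf("Bland-Altman: bias %.3f, LoA [%.3f, %.3f]",
        object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' Per-plate Z' quality scatter
#'
#' One point per plate with the conventional Z' = 0.5 quality threshold
#' marked, the standard whole-screen QC overview.
#'
#' @param qc A [plate_qc()] table.
#' @param threshold Threshold line (default 0.5).
#' @return A ggplot object.
#' @export
plot_plate_qc <- function(qc, threshold = 0.5) {
  ggplot2::ggplot(qc, ggplot2::aes(x = .data$plate_id, y = .data$z_prime,
    colour = .data$pass)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed", colour = "red") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "steelblue", `FALSE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "Z'", colour = "QC pass") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Normalised dual-reporter time courses
#'
#' DMSO-normalised fluorescence ratio against time for the SPLIF and
#' SPLOOF reporters of one or more compounds, with the decision
#' boundary at a ratio of 1 marked. Splicing modulators show the
#' characteristic transient SPLOOF rise above 1 with SPLIF held below.
#'
#' @param normalized Output of [normalize_timecourse()].
#' @param compounds Optional compound ids to restrict to.
#' @return A ggplot object.
#' @export
plot_reporter_traces <- function(normalized, compounds = NULL) {
  if (!is.null(compounds)) {
    normalized <- dplyr::filter(normalized, .data$compound_id %in% compounds)
  }
  ggplot2::ggplot(normalized, ggplot2::aes(
    x = .data$time_min / 60, y = .data$f_norm,
    colour = .data$reporter,
    group = interaction(.data$well, .data$reporter, .data$replicate_id))) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_grid(compound_id ~ strain_id) +
    ggplot2::labs(x = "Time (h)", y = "Fluorescence ratio to DMSO",
      colour = "Reporter") +
    ggplot2::theme_minimal()
}
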