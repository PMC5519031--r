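#' Scatter of tumor IHC H-score against a CTC metric
#'
#' The compartment-concordance diagnostic: one point per patient,
#' tumor H-score on x, the chosen CTC metric on y, colored by subtype
#' when present. Patients with a missing metric (no CTCs) are dropped.
#'
#' @param cohort A cohort table.
#' @param metric Unquoted CTC metric column (default `ctc_h_score`).
#' @return A ggplot object.
#' @examples
#' plot_compartment_concordance(fixture_patient_cohort())
#' @export
plot_compartment_concordance <- function(cohort, metric = ctc_h_score) {
  q <- enquo(metric)
  d <- dplyr::filter(cohort, !is.na(!!q))
  aes <- if ("subtype" %in% names(cohort)) {
    ggplot2::aes(x = .data$ihc_h_score, y = !!q, colour = .data$subtype)
  } else {
    ggplot2::aes(x = .data$ihc_h_score, y = !!q)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(alpha = 0.8, size = 2) +
    ggplot2::labs(x = "Tumor IHC H-score",
                  y = rlang::as_label(q),
                  colour = "Subtype") +
    ggplot2::theme_minimal()
}

#' Per-sample 5T4 intensity scatter with category thresholds
#'
#' One jittered point per cell on a log-scaled intensity axis, with
#' horizontal lines at the negative/low/medium/high boundaries —
#' useful for eyeballing control-line separation and synthetic-cohort
#' realism.
#'
#' @param cells A per-cell table with `sample_id` and `t5t4`.
#' @param nlmh An [nlmh_thresholds()] object.
#' @return A ggplot object.
#' @examples
#' cells <- simulate_line_cells(control_line_profiles()[4, ], 200, seed = 1)
#' plot_intensity_distributions(cells)
#' @export
plot_intensity_distributions <- function(cells, nlmh = nlmh_thresholds()) {
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$sample_id, y = .data$t5t4)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          colour = "red", linewidth = 0.3) +
    ggplot2::geom_hline(
      yintercept = c(nlmh$low_min, nlmh$medium_min, nlmh$high_min),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "5T4 intensity (fluorescence units)") +
    ggplot2::theme_minimal()
}

#' @describeIn run_recovery Histogram of recovered rho across
#'   replicates with the mean (solid) marked.
#' @param object A `ctc_recovery` object.
#' @export
autoplot.ctc_recovery <- function(object, ...) {
  d <- dplyr::filter(object$estimates, !is.na(.data$rho))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = mean(d$rho), linewidth = 0.8) +
    ggplot2::labs(x = "Recovered Spearman rho", y = "Cohorts") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
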