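#' Intensity category thresholds (negative/low/medium/high)
#'
#' Boundaries of the per-cell 5T4 fluorescence-intensity categories used
#' throughout the CTC assay: negative `[0, 3)`, low `[3, 8)`, medium
#' `[8, 20)`, high `[20, Inf)`, in fluorescence units. Bins are treated
#' as half-open continuous intervals, so an intensity of exactly 3.00
#' is "low" and 20.00 is "high".
#'
#' @param low_min,medium_min,high_min Lower bounds of the low, medium
#'   and high categories, in fluorescence units.
#' @return A list of class `nlmh_thresholds`.
#' @examples
#' nlmh_thresholds()
#' @export
nlmh_thresholds <- function(low_min = 3, medium_min = 8, high_min = 20) {
  if (!(0 < low_min && low_min < medium_min && medium_min < high_min)) {
    abort("thresholds must satisfy 0 < low_min < medium_min < high_min")
  }
  structure(
    list(low_min = low_min, medium_min = medium_min, high_min = high_min),
    class = "nlmh_thresholds"
  )
}

#' Immunofluorescence gating thresholds for cell classification
#'
#' A cell is called a CTC when it is cytokeratin positive
#' (`ck >= ck_min`), CD45 negative (`cd45 <= cd45_max`), DAPI positive
#' (`dapi >= dapi_min`) and has an intact nucleus; any cell with
#' `cd45 > cd45_max` is a white blood cell (WBC). The defaults separate
#' the synthetic channel model cleanly (they sit beyond the 99th
#' percentile of the off-target channel for each population); gating of
#' real platform data should use instrument-specific values.
#'
#' @param ck_min Minimum cytokeratin intensity for a CTC call.
#' @param cd45_max Maximum CD45 intensity compatible with a CTC call.
#' @param dapi_min Minimum DAPI intensity for an evaluable nucleus.
#' @param t5t4_negative_cutoff Intensity below which a cell counts as
#'   5T4 negative. The default is the population mean 5T4 intensity of
#'   the negative control line profile (see
#'   [control_line_profiles()]), the assay's definition of negativity;
#'   it can be re-derived from observed control cells with
#'   [derive_negative_cutoff()].
#' @return A list of class `gating_thresholds`.
#' @examples
#' gating_thresholds()
#' @export
gating_thresholds <- function(ck_min = 5, cd45_max = 5, dapi_min = 5,
                              t5t4_negative_cutoff = default_negative_cutoff()) {
  vals <- c(ck_min = ck_min, cd45_max = cd45_max, dapi_min = dapi_min,
            t5t4_negative_cutoff = t5t4_negative_cutoff)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("gating thresholds must be finite and non-negative")
  }
  structure(as.list(vals), class = "gating_thresholds")
}

#' Calibrated control cell line intensity profiles
#'
#' Log-normal 5T4 intensity profiles for the four control lines used to
#' anchor the assay: a negative, low, medium and high expressing line.
#' The log-means were calibrated once, numerically, so that the
#' *population* H-score of each line under the default category
#' thresholds reproduces the line's reference H-score (58, 102, 201 and
#' 256). For the negative line the reference score is defined with the
#' assay's negativity rule (cells below the line's own population mean
#' are scored category 0); for the other lines the plain category bins
#' apply. All lines share `log_sd = 1`, reflecting the wide intra-line
#' spread seen in per-cell scatter of clonal control populations.
#'
#' `ck_level` and `cd45_level` are the median cytokeratin and CD45
#' intensities used when synthesizing full channel records; tumor lines
#' carry no CD45.
#'
#' @return A tibble with one row per control line: `name`,
#'   `expression_class`, `log_mean`, `log_sd`, `ck_level`, `cd45_level`
#'   and `reference_h_score`.
#' @examples
#' control_line_profiles()
#' @export
control_line_profiles <- function() {
  tibble::tibble(
    name = c("H460", "H2122", "H1975", "H226"),
    expression_class = c("negative", "low", "medium", "high"),
    # calibrated: population H-score = reference_h_score (see vignette)
    log_mean = c(1.321927, 1.518572, 2.637779, 3.412537),
    log_sd = 1,
    ck_level = 50,
    cd45_level = 0,
    reference_h_score = c(58, 102, 201, 256)
  )
}

#' Default 5T4 negativity cutoff
#'
#' The assay defines 5T4 negativity by the mean intensity of the
#' negative control line. This returns that mean for the shipped
#' calibrated profile, analytically: `exp(log_mean + log_sd^2 / 2)`.
#'
#' @return A single fluorescence-unit value (about 6.18).
#' @examples
#' default_negative_cutoff()
#' @export
default_negative_cutoff <- function() {
  p <- control_line_profiles()
  neg <- p[p$expression_class == "negative", ]
  exp(neg$log_mean + neg$log_sd^2 / 2)
}

#' Derive the 5T4 negativity cutoff from negative-line cells
#'
#' Returns the arithmetic mean 5T4 intensity of a set of observed
#' negative control line cells, the operational definition of the
#' negativity cutoff.
#'
#' @param cells A data frame of cell records with a `t5t4` column, or a
#'   numeric vector of intensities.
#' @return A single non-negative number.
#' @examples
#' derive_negative_cutoff(data.frame(t5t4 = c(1, 2, 3)))
#' @export
derive_negative_cutoff <- function(cells) {
  x <- if (is.data.frame(cells)) cells$t5t4 else cells
  if (is.null(x) || length(x) == 0) abort("no cells supplied")
  if (any(is.na(x)) || any(x < 0)) abort("intensities must be non-negative and non-missing")
  mean(x)
}

#' Categorize 5T4 intensities into the 0-3 expression categories
#'
#' Maps non-negative intensities to categories 0 (negative), 1 (low),
#' 2 (medium), 3 (high) using half-open bins at the category
#' thresholds. An optional negativity `cutoff` forces any intensity
#' below it to category 0 regardless of the bins (the assay's
#' negative-line-mean rule); the default `cutoff = 0` applies the bins
#' alone.
#'
#' @param x Numeric vector of non-negative intensities.
#' @param nlmh An [nlmh_thresholds()] object.
#' @param cutoff Negativity cutoff in fluorescence units.
#' @return An integer vector in `0:3`, same length as `x`.
#' @examples
#' categorize_intensity(c(0, 2.99, 3, 8, 19.99, 20))
#' @export
categorize_intensity <- function(x, nlmh = nlmh_thresholds(), cutoff = 0) {
  if (any(is.na(x)) || any(x < 0)) abort("intensities must be non-negative and non-missing")
  breaks <- c(nlmh$low_min, nlmh$medium_min, nlmh$high_min)
  k <- findInterval(x, breaks)
  k[x < cutoff] <- 0L
  as.integer(k)
}
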