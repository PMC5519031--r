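#' Correlate tumor IHC H-score with the CTC metric panel
#'
#' Runs [spearman_test()] of the tumor IHC H-score against each CTC
#' metric, over the whole cohort and within each subtype. Pairs with a
#' missing value in either member are dropped per comparison (samples
#' with zero CTCs have `NA` H-scores). This reproduces the
#' compartment-concordance correlation table of the reference study.
#'
#' @param cohort A cohort table (columns of
#'   [fixture_patient_cohort()]).
#' @param metrics Character vector of cohort columns to correlate with
#'   `ihc_h_score`.
#' @param by_subtype Also compute within-subtype correlations.
#' @param tie_correction Passed to [spearman_test()].
#' @return A tibble: `indication`, `parameter`, `rho`, `n`, `p_value`,
#'   `method`.
#' @examples
#' correlate_compartments(fixture_patient_cohort())
#' @export
correlate_compartments <- function(cohort,
                                   metrics = c("ctc_per_ml", "ctc_h_score",
                                               "cluster_weighted_h_score",
                                               "cluster_weighted_burden_per_ml",
                                               "burden_per_ml"),
                                   by_subtype = TRUE,
                                   tie_correction = FALSE) {
  cohort <- tibble::as_tibble(cohort)
  missing_cols <- setdiff(c("ihc_h_score", metrics), names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  subsets <- list(all = cohort)
  if (by_subtype && "subtype" %in% names(cohort)) {
    for (ty in unique(cohort$subtype)) subsets[[ty]] <- cohort[cohort$subtype == ty, ]
  }
  purrr::imap(subsets, function(d, ind) {
    purrr::map(metrics, function(m) {
      st <- spearman_test(d$ihc_h_score, d[[m]], tie_correction = tie_correction)
      tibble::tibble(indication = ind, parameter = m, rho = st$rho,
                     n = st$n, p_value = st$p_value, method = st$method)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Mean, SEM and subtype comparison for each CTC metric
#'
#' Per-subtype mean and standard error for each requested metric, with
#' a two-sided Mann-Whitney p-value comparing the two subtypes
#' (missing values dropped per metric). Reported means mirror the
#' reference tables only loosely: published per-subtype summaries are
#' not exactly recomputable from the published per-sample panel, so
#' these summaries are descriptive output, not asserted reproductions.
#'
#' @param cohort A cohort table with a `subtype` column.
#' @param metrics Character vector of metric columns.
#' @return A tibble: `metric`, `subtype`, `n`, `mean`, `sem`,
#'   `p_value` (repeated within metric; `NA` unless exactly two
#'   subtypes are present).
#' @examples
#' subtype_summary(fixture_patient_cohort(), "ihc_h_score")
#' @export
subtype_summary <- function(cohort,
                            metrics = c("ihc_h_score", "ctc_per_ml",
                                        "ctc_h_score", "cluster_weighted_h_score",
                                        "burden_per_ml",
                                        "cluster_weighted_burden_per_ml")) {
  cohort <- tibble::as_tibble(cohort)
  purrr::map(metrics, function(m) {
    per <- cohort |>
      dplyr::filter(!is.na(.data[[m]])) |>
      dplyr::reframe(mean_sem(.data[[m]]), .by = "subtype") |>
      dplyr::mutate(metric = m, .before = 1)
    p <- if (length(unique(per$subtype)) == 2) {
      compare_groups(cohort, .data[[m]], .data$subtype, "mann_whitney")$p_value
    } else {
      NA_real_
    }
    dplyr::mutate(per, p_value = p)
  }) |> purrr::list_rbind()
}

validate_fixture_set <- function(fixtures) {
  specs <- list(
    cell_lines = list(n = 4, cols = c("cell_line", "qrt_pcr", "western_blot", "icc_rank")),
    tumor_panel = list(n = 21, cols = c("sample", "subtype", "qrt_pcr",
                                        "western_blot", "ihc_h_score")),
    patient_cohort = list(n = 35, cols = c("subtype", "ihc_h_score", "ctc_per_ml",
                                           "ctc_h_score", "cluster_weighted_h_score",
                                           "burden_per_ml",
                                           "cluster_weighted_burden_per_ml",
                                           "pct_negative"))
  )
  for (name in names(specs)) {
    tab <- fixtures[[name]]
    if (is.null(tab)) abort(paste0("fixture set lacks '", name, "'"))
    sp <- specs[[name]]
    missing_cols <- setdiff(sp$cols, names(tab))
    if (length(missing_cols) > 0) {
      abort(paste0("fixture '", name, "' lacks column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    if (nrow(tab) != sp$n) {
      abort(paste0("fixture '", name, "' has ", nrow(tab), " rows, expected ", sp$n))
    }
  }
  invisible(fixtures)
}

#' Run the full fixture analysis
#'
#' Recomputes, from the shipped reference tables (or an equivalently
#' shaped fixture set), every headline statistic of the study this
#' package models: the control cell line rank correlations (exact
#' permutation p-values at n = 4), the 21-tumor H-score vs
#' qRT-PCR/western-blot correlations overall and by subtype, the
#' 35-patient tumor-vs-CTC compartment correlations, the positivity
#' concordance counts, and the per-subtype metric summaries.
#'
#' @param fixtures A named list with tibbles `cell_lines`,
#'   `tumor_panel`, `patient_cohort`; defaults to the shipped tables.
#' @return An object of class `ctc_report`: a list with elements
#'   `cell_line_correlations`, `tumor_correlations`,
#'   `compartment_correlations`, `concordance`, `subtype_summary`,
#'   `cohort` (the per-sample panel) and `provenance`.
#' @examples
#' rep <- analyze_fixtures()
#' rep$concordance
#' @export
analyze_fixtures <- function(fixtures = list(cell_lines = fixture_cell_lines(),
                                             tumor_panel = fixture_tumor_panel(),
                                             patient_cohort = fixture_patient_cohort())) {
  validate_fixture_set(fixtures)
  t1 <- fixtures$cell_lines
  t4 <- fixtures$tumor_panel
  t6 <- fixtures$patient_cohort

  cell_line_correlations <- purrr::map(
    c(qrt_pcr = "qrt_pcr", western_blot = "western_blot"),
    \(m) {
      st <- spearman_test(t1$icc_rank, t1[[m]])
      tibble::tibble(parameter_1 = "icc_rank", parameter_2 = m, rho = st$rho,
                     n = st$n, p_value = st$p_value, method = st$method)
    }
  ) |> purrr::list_rbind()

  tumor_subsets <- list(all = t4, SCC = t4[t4$subtype == "SCC", ],
                        AC = t4[t4$subtype == "AC", ])
  tumor_correlations <- purrr::imap(tumor_subsets, function(d, ind) {
    purrr::map(c("western_blot", "qrt_pcr"), function(m) {
      st <- spearman_test(d$ihc_h_score, d[[m]])
      tibble::tibble(indication = ind, parameter_1 = "ihc_h_score",
                     parameter_2 = m, rho = st$rho, n = st$n,
                     p_value = st$p_value, method = st$method)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  structure(list(
    cell_line_correlations = cell_line_correlations,
    tumor_correlations = tumor_correlations,
    compartment_correlations = correlate_compartments(t6),
    concordance = concordance_counts(t6),
    subtype_summary = subtype_summary(t6),
    cohort = t6,
    provenance = list(fixture_checksums = as.list(fixture_checksums),
                      package_version = as.character(utils::packageVersion("ctcscore")))
  ), class = "ctc_report")
}

#' @export
print.ctc_report <- function(x, ...) {
  cat("CTC / tumor 5T4 analysis report\n")
  cat("\nCell line rank correlations:\n")
  print(x$cell_line_correlations)
  cat("\nTumor panel correlations (IHC H-score vs orthogonal assays):\n")
  print(x$tumor_correlations)
  cat("\nTumor vs CTC compartment correlations:\n")
  print(x$compartment_correlations, n = Inf)
  cat("\nPositivity concordance:\n")
  print(x$concordance)
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Serializes a `ctc_report` deterministically (no timestamps); `NA`
#' values are rendered as JSON `"NA"` strings so every printed table
#' cell is preserved. Rerunning on identical input yields
#' byte-identical output.
#'
#' @param report A `ctc_report` from [analyze_fixtures()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "ctc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "string", dataframe = "rows")
  invisible(path)
}

#' Recover the latent tumor-CTC coupling from simulated cohorts
#'
#' The generator's validation harness: simulates `n_replicates`
#' cohorts under `config`, runs each through the full scoring pipeline
#' (cells -> gating -> entities -> metrics), and correlates the tumor
#' IHC H-score with the CTC H-score by [spearman_rho()] within each
#' cohort. The distribution of recovered rho values is the pipeline's
#' operating characteristic at the configured `coupling_rho`; note the
#' recovered value estimates the rank correlation of the *observable*
#' metric panel, which is attenuated relative to the latent coupling
#' by finite per-patient CTC counts (see the methods vignette).
#'
#' Replicate seeds are derived as `config$seed + replicate`.
#'
#' @param config A [cohort_config()].
#' @param n_replicates Number of cohorts to simulate (>= 1).
#' @param metric Cohort column correlated with `ihc_h_score`.
#' @return An object of class `ctc_recovery`: list with `estimates` (a
#'   tibble: `replicate`, `seed`, `n_pairs`, `rho`), `coupling_rho`
#'   and `metric`. `glance()` gives the mean/SD summary.
#' @examples
#' rec <- run_recovery(cohort_config(n_patients = 20, seed = 3), n_replicates = 5)
#' glance(rec)
#' @export
run_recovery <- function(config = cohort_config(), n_replicates = 200,
                         metric = "ctc_h_score") {
  stopifnot(inherits(config, "cohort_config"))
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  estimates <- purrr::map(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_cohort(cfg)
    co <- sim$cohort
    ok <- stats::complete.cases(co$ihc_h_score, co[[metric]])
    rho <- if (sum(ok) >= 3) spearman_rho(co$ihc_h_score, co[[metric]]) else NA_real_
    tibble::tibble(replicate = r, seed = cfg$seed, n_pairs = sum(ok), rho = rho)
  }) |> purrr::list_rbind()
  structure(list(estimates = estimates, coupling_rho = config$coupling_rho,
                 metric = metric),
            class = "ctc_recovery")
}

#' @rdname run_recovery
#' @param x A `ctc_recovery` object.
#' @param ... Unused.
#' @export
glance.ctc_recovery <- function(x, ...) {
  r <- x$estimates$rho
  tibble::tibble(
    coupling_rho = x$coupling_rho,
    metric = x$metric,
    n_replicates = length(r),
    n_estimable = sum(!is.na(r)),
    mean_rho = mean(r, na.rm = TRUE),
    sd_rho = stats::sd(r, na.rm = TRUE)
  )
}

#' @export
print.ctc_recovery <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("Coupling recovery: coupling_rho = %.3f, mean recovered ",
                     "rho = %.3f (sd %.3f) over %d cohorts [%s]\n"),
              g$coupling_rho, g$mean_rho, g$sd_rho, g$n_replicates, x$metric))
  invisible(x)
}
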