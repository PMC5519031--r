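#' Reference data tables shipped with the package
#'
#' Three small tables transcribed from the published study that this
#' package's statistics reproduce, frozen with checksums so an
#' accidental edit is caught at load time:
#'
#' * `fixture_cell_lines()` — the four control cell lines with their
#'   5T4 measurements by qRT-PCR (relative to a universal RNA
#'   control), western blot (relative to GAPDH and the high line) and
#'   the 1-4 immunocytochemistry visual rank.
#' * `fixture_tumor_panel()` — 21 NSCLC tumors (adenocarcinoma and
#'   squamous cell carcinoma) with qRT-PCR, western blot and
#'   pathologist IHC H-score.
#' * `fixture_patient_cohort()` — the 35-patient cohort (25
#'   adenocarcinoma, 10 squamous) with the tumor IHC H-score and the
#'   full per-sample CTC metric panel; `NA` marks the % 5T4-negative
#'   entry of samples with zero CTCs.
#'
#' @return A tibble (4, 21 and 35 rows respectively).
#' @examples
#' fixture_patient_cohort()
#' @name fixtures
NULL

fixture_checksums <- c(
  cell_lines = "43c5644919f7b56c5276d225fa6d8e6e",
  tumor_panel = "a44eaf50394476595291129f74a785ce",
  patient_cohort = "cc2c2d477f222f8e20b7e82213aa8cb0"
)

read_fixture <- function(name) {
  path <- system.file("extdata", paste0(name, ".csv"), package = "ctcscore",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(fixture_checksums[[name]]))) {
    abort(paste0("fixture '", name, "' failed its checksum; the shipped ",
                 "reference table appears to have been modified"))
  }
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname fixtures
#' @export
fixture_cell_lines <- function() read_fixture("cell_lines")

#' @rdname fixtures
#' @export
fixture_tumor_panel <- function() read_fixture("tumor_panel")

#' @rdname fixtures
#' @export
fixture_patient_cohort <- function() read_fixture("patient_cohort")
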