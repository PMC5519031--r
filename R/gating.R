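#' Classify cell records into CTC / WBC / other
#'
#' Applies the conjunctive immunofluorescence gate to each per-cell
#' record: a CTC is cytokeratin positive, CD45 negative, DAPI positive
#' and has an intact nucleus; any CD45-positive cell is a WBC;
#' everything else is "other". The 5T4 channel plays no role in CTC
#' identity.
#'
#' @param cells A data frame with columns `ck`, `cd45`, `dapi` and
#'   logical `intact_nucleus` (the per-cell schema of
#'   [simulate_cohort()]).
#' @param gates A [gating_thresholds()] object.
#' @return `cells` with an added character column `label` in
#'   `c("CTC", "WBC", "other")`.
#' @examples
#' cells <- tibble::tibble(
#'   sample_id = "s1", cell_id = c("c1", "c2"),
#'   dapi = c(100, 90), ck = c(40, 0.2), cd45 = c(0, 60),
#'   t5t4 = c(12, 0.5), intact_nucleus = TRUE
#' )
#' classify_cells(cells)
#' @export
classify_cells <- function(cells, gates = gating_thresholds()) {
  needed <- c("ck", "cd45", "dapi", "intact_nucleus")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols) > 0) {
    abort(paste0("cells table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  intens <- c(cells$ck, cells$cd45, cells$dapi)
  if (any(is.na(intens)) || any(intens < 0)) {
    abort("channel intensities must be non-negative and non-missing")
  }
  is_ctc <- cells$ck >= gates$ck_min &
    cells$cd45 <= gates$cd45_max &
    cells$dapi >= gates$dapi_min &
    cells$intact_nucleus
  label <- dplyr::case_when(
    is_ctc ~ "CTC",
    cells$cd45 > gates$cd45_max ~ "WBC",
    .default = "other"
  )
  dplyr::mutate(tibble::as_tibble(cells), label = label)
}

#' Group CTC records into single-cell and cluster entities
#'
#' Cells sharing a non-missing `cluster_id` within a sample form one
#' entity (a CTC cluster); cells with missing `cluster_id` are
#' singleton entities. The entity intensity is the arithmetic mean of
#' its members' 5T4 intensities, so a cluster counts as a single unit
#' in entity-level ("plain") scoring while its member intensities stay
#' available for cluster-weighted scoring.
#'
#' @param cells A data frame of CTC records with columns `sample_id`,
#'   `cell_id`, `cluster_id` (NA for single cells) and `t5t4`. If a
#'   `label` column is present only rows labelled `"CTC"` are used.
#' @return A tibble with one row per entity: `sample_id`, `entity_id`,
#'   `cluster_id`, `n_cells`, `entity_intensity`, and a list-column
#'   `member_t5t4` of member intensities.
#' @examples
#' ctcs <- tibble::tibble(
#'   sample_id = "s1", cell_id = paste0("c", 1:4),
#'   cluster_id = c(NA, "k1", "k1", "k1"), t5t4 = c(5, 1, 1, 10)
#' )
#' assemble_entities(ctcs)
#' @export
assemble_entities <- function(cells) {
  cells <- tibble::as_tibble(cells)
  if ("label" %in% names(cells)) {
    cells <- dplyr::filter(cells, .data$label == "CTC")
  }
  if (nrow(cells) == 0) {
    return(tibble::tibble(
      sample_id = character(), entity_id = character(),
      cluster_id = character(), n_cells = integer(),
      entity_intensity = double(), member_t5t4 = list()
    ))
  }
  if (any(is.na(cells$t5t4)) || any(cells$t5t4 < 0)) {
    abort("t5t4 intensities must be non-negative and non-missing")
  }
  # a cluster id must not span samples
  spans <- cells |>
    dplyr::filter(!is.na(.data$cluster_id)) |>
    dplyr::distinct(.data$sample_id, .data$cluster_id) |>
    dplyr::count(.data$cluster_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(spans) > 0) {
    abort(paste0("cluster_id shared across samples: ",
                 paste(spans$cluster_id, collapse = ", ")))
  }
  cells |>
    dplyr::mutate(
      .entity = dplyr::if_else(is.na(.data$cluster_id),
                               paste0("single:", .data$cell_id),
                               paste0("cluster:", .data$cluster_id))
    ) |>
    dplyr::summarise(
      cluster_id = .data$cluster_id[1],
      n_cells = dplyr::n(),
      entity_intensity = mean(.data$t5t4),
      member_t5t4 = list(.data$t5t4),
      .by = c("sample_id", ".entity")
    ) |>
    dplyr::rename(entity_id = ".entity")
}
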