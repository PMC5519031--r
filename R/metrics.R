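#' Tumor IHC H-score from membrane staining fractions
#'
#' The pathologist's semi-quantitative index for tissue sections:
#' `3 * pct_strong + 2 * pct_moderate + 1 * pct_weak`, where the three
#' arguments are the percentages of malignant cell membranes staining
#' weakly, moderately and strongly. Range 0 (no staining) to 300 (all
#' membranes strong).
#'
#' @param pct_weak,pct_moderate,pct_strong Percentages in `[0, 100]`
#'   whose sum must not exceed 100. Vectorized.
#' @return Numeric vector of H-scores in `[0, 300]`.
#' @examples
#' ihc_h_score(30, 20, 10)   # 100
#' ihc_h_score(0, 0, 100)    # 300
#' @export
ihc_h_score <- function(pct_weak, pct_moderate, pct_strong) {
  p <- cbind(pct_weak, pct_moderate, pct_strong)
  if (any(is.na(p)) || any(p < 0) || any(p > 100)) {
    abort("staining percentages must lie in [0, 100]")
  }
  tot <- rowSums(p)
  if (any(tot > 100 + 1e-8)) {
    abort("staining percentages must sum to at most 100")
  }
  as.numeric(3 * pct_strong + 2 * pct_moderate + pct_weak)
}

#' H-score from intensity categories
#'
#' Given items assigned to intensity categories 0-3 (optionally with
#' weights), computes `1 * p1 + 2 * p2 + 3 * p3` where `p_k` is the
#' percentage of total weight falling in category `k`. This is the
#' common core of the CTC H-score variants.
#'
#' @param category Integer vector with values in `0:3`.
#' @param weight Optional non-negative weights (recycled); default 1.
#' @return A single H-score in `[0, 300]`, or `NA` when the total
#'   weight is zero (no evaluable items).
#' @examples
#' h_score_from_categories(c(0, 1, 2, 3))  # 150
#' @export
h_score_from_categories <- function(category, weight = 1) {
  if (length(category) == 0) return(NA_real_)
  if (any(is.na(category)) || any(!category %in% 0:3)) {
    abort("categories must be integers in 0:3")
  }
  weight <- rep_len(weight, length(category))
  if (any(is.na(weight)) || any(weight < 0)) abort("weights must be non-negative")
  tot <- sum(weight)
  if (tot == 0) return(NA_real_)
  100 * sum(category * weight) / tot
}

#' Per-sample CTC 5T4 metrics from assembled entities
#'
#' These functions compute the per-sample metric panel from the entity
#' table produced by [assemble_entities()]:
#'
#' * `ctc_h_score()` — each entity (single cell or whole cluster)
#'   weighted once, categorized by its mean intensity.
#' * `cluster_weighted_h_score()` — clusters expanded to their member
#'   cells, each cell categorized by its own intensity. The two scores
#'   coincide exactly when the sample has no clusters.
#' * `burden_per_ml()` — sum of entity intensities divided by blood
#'   volume; `cluster_weighted_burden_per_ml()` sums every member
#'   cell's intensity instead. Sub-cutoff (5T4-negative) cells are
#'   included in both sums.
#' * `ctc_per_ml()` — member-cell count (clusters count each cell)
#'   divided by blood volume.
#' * `pct_negative_ctcs()` — percentage of member cells with intensity
#'   below the negativity cutoff.
#'
#' H-scores and the negative percentage are `NA` for samples with no
#' CTCs; counts and burdens are 0 there.
#'
#' @param entities An entity tibble from [assemble_entities()] (one
#'   sample's entities).
#' @param nlmh An [nlmh_thresholds()] object.
#' @param cutoff 5T4 negativity cutoff in fluorescence units; cells
#'   below it are category 0 / counted as negative.
#' @param volume_ml Analyzed blood volume in mL (> 0).
#' @return A single number (`NA` where noted above).
#' @examples
#' ctcs <- tibble::tibble(
#'   sample_id = "s1", cell_id = paste0("c", 1:3),
#'   cluster_id = "k1", t5t4 = c(2.5, 2.5, 25)
#' )
#' e <- assemble_entities(ctcs)
#' ctc_h_score(e)               # one entity, mean 10 -> medium -> 200
#' cluster_weighted_h_score(e)  # cells 0/0/high -> 100
#' @name ctc_metrics
NULL

member_intensities <- function(entities) {
  if (nrow(entities) == 0) return(numeric())
  unlist(entities$member_t5t4, use.names = FALSE)
}

#' @rdname ctc_metrics
#' @export
ctc_h_score <- function(entities, nlmh = nlmh_thresholds(),
                        cutoff = default_negative_cutoff()) {
  if (nrow(entities) == 0) return(NA_real_)
  h_score_from_categories(categorize_intensity(entities$entity_intensity, nlmh, cutoff))
}

#' @rdname ctc_metrics
#' @export
cluster_weighted_h_score <- function(entities, nlmh = nlmh_thresholds(),
                                     cutoff = default_negative_cutoff()) {
  x <- member_intensities(entities)
  if (length(x) == 0) return(NA_real_)
  h_score_from_categories(categorize_intensity(x, nlmh, cutoff))
}

#' @rdname ctc_metrics
#' @export
burden_per_ml <- function(entities, volume_ml = 1) {
  if (volume_ml <= 0) abort("volume_ml must be positive")
  sum(entities$entity_intensity) / volume_ml
}

#' @rdname ctc_metrics
#' @export
cluster_weighted_burden_per_ml <- function(entities, volume_ml = 1) {
  if (volume_ml <= 0) abort("volume_ml must be positive")
  sum(member_intensities(entities)) / volume_ml
}

#' @rdname ctc_metrics
#' @export
ctc_per_ml <- function(entities, volume_ml = 1) {
  if (volume_ml <= 0) abort("volume_ml must be positive")
  sum(entities$n_cells) / volume_ml
}

#' @rdname ctc_metrics
#' @export
pct_negative_ctcs <- function(entities, cutoff = default_negative_cutoff()) {
  x <- member_intensities(entities)
  if (length(x) == 0) return(NA_real_)
  100 * mean(x < cutoff)
}

#' Score one sample's cell records into the CTC metric panel
#'
#' Runs the full per-sample chain on raw per-cell records: gate cells
#' ([classify_cells()]), assemble CTC entities
#' ([assemble_entities()]), and compute the metric panel. Samples with
#' zero gated CTCs get `NA` H-scores and negative percentage, and zero
#' counts and burdens.
#'
#' @param cells Per-cell records for a single sample (per-cell schema
#'   of [simulate_cohort()]).
#' @param gates A [gating_thresholds()] object; its
#'   `t5t4_negative_cutoff` is the negativity cutoff used for
#'   categorization and the negative percentage.
#' @param nlmh An [nlmh_thresholds()] object.
#' @param volume_ml Analyzed blood volume in mL.
#' @return A one-row tibble: `sample_id`, `n_ctc`, `n_entities`,
#'   `ctc_per_ml`, `ctc_h_score`, `cluster_weighted_h_score`,
#'   `burden_per_ml`, `cluster_weighted_burden_per_ml`,
#'   `pct_negative`.
#' @seealso [score_cohort()] for many samples at once.
#' @export
score_sample <- function(cells, gates = gating_thresholds(),
                         nlmh = nlmh_thresholds(), volume_ml = 1) {
  cells <- tibble::as_tibble(cells)
  if (!"sample_id" %in% names(cells)) abort("cells table lacks a sample_id column")
  sid <- unique(cells$sample_id)
  if (length(sid) > 1) abort("score_sample() expects records from a single sample")
  if (length(sid) == 0) sid <- NA_character_
  gated <- classify_cells(cells, gates)
  ent <- assemble_entities(gated)
  cutoff <- gates$t5t4_negative_cutoff
  tibble::tibble(
    sample_id = sid,
    n_ctc = sum(ent$n_cells),
    n_entities = nrow(ent),
    ctc_per_ml = ctc_per_ml(ent, volume_ml),
    ctc_h_score = ctc_h_score(ent, nlmh, cutoff),
    cluster_weighted_h_score = cluster_weighted_h_score(ent, nlmh, cutoff),
    burden_per_ml = burden_per_ml(ent, volume_ml),
    cluster_weighted_burden_per_ml = cluster_weighted_burden_per_ml(ent, volume_ml),
    pct_negative = pct_negative_ctcs(ent, cutoff)
  )
}

#' Score every sample in a multi-sample cell table
#'
#' @inheritParams score_sample
#' @return A tibble with one [score_sample()] row per `sample_id`, in
#'   first-appearance order.
#' @export
score_cohort <- function(cells, gates = gating_thresholds(),
                         nlmh = nlmh_thresholds(), volume_ml = 1) {
  cells <- tibble::as_tibble(cells)
  if (!"sample_id" %in% names(cells)) abort("cells table lacks a sample_id column")
  unique(cells$sample_id) |>
    purrr::map(\(id) score_sample(cells[cells$sample_id == id, , drop = FALSE],
                                  gates, nlmh, volume_ml)) |>
    purrr::list_rbind()
}
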