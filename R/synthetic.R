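#' Configuration for the synthetic patient cohort generator
#'
#' Bundles every tunable of the generative model with defaults chosen
#' to emulate the reference 35-patient NSCLC cohort:
#'
#' * CTC counts per mL are negative binomial (`ctc_rate_mean`,
#'   dispersion/size `ctc_rate_dispersion`); the defaults give a mean
#'   near 48 with about 8% zero-CTC patients and a long tail spanning
#'   the observed 0-346 range.
#' * Each CTC independently joins a cluster with `cluster_prob`;
#'   cluster sizes are `2 + Geometric(cluster_size_geom_prob)`.
#' * Per-cell 5T4 intensity follows a two-component log-normal mixture
#'   (`intensity_mixture`: columns `weight`, `log_mean`, `log_sd`)
#'   whose log-means are shifted by `intensity_shift` times the
#'   patient's latent CTC expression, so between-patient expression
#'   differences are comparable to the span of the four control lines.
#' * Latent tumor and CTC expression are standard bivariate normal
#'   with correlation `coupling_rho` — the ground-truth coupling that
#'   concordance analyses try to recover.
#' * The tumor compartment maps latent tumor expression through
#'   [latent_to_ihc()] into membrane-fraction triples and an IHC
#'   H-score.
#' * `wbc_records_mean` white-blood-cell records (Poisson) are added
#'   per sample so gating has something to reject.
#'
#' @param n_patients Number of patients (>= 1).
#' @param seed Integer seed; a single generator is seeded once per
#'   [simulate_cohort()] run.
#' @param blood_volume_ml Analyzed blood volume per sample, mL.
#' @param ctc_rate_mean,ctc_rate_dispersion Negative binomial mean (per
#'   mL) and size parameter of the CTC count law.
#' @param cluster_prob Probability a CTC is in a cluster.
#' @param cluster_size_geom_prob Geometric parameter of cluster sizes.
#' @param subtype_fraction Fraction of adenocarcinoma patients;
#'   allocation is deterministic (`round(n * fraction)` AC patients).
#' @param coupling_rho Latent tumor-CTC coupling in `[-1, 1]`.
#' @param intensity_shift Log-intensity shift per unit latent CTC
#'   expression.
#' @param intensity_mixture Data frame with columns `weight`,
#'   `log_mean`, `log_sd`; weights must sum to 1.
#' @param wbc_records_mean Mean number of WBC records per sample.
#' @return A list of class `cohort_config`.
#' @examples
#' cohort_config(n_patients = 10, seed = 1)
#' @export
cohort_config <- function(n_patients = 35,
                          seed = 20170720,
                          blood_volume_ml = 1,
                          ctc_rate_mean = 48,
                          ctc_rate_dispersion = 0.6,
                          cluster_prob = 0.3,
                          cluster_size_geom_prob = 0.5,
                          subtype_fraction = 25 / 35,
                          coupling_rho = 0,
                          intensity_shift = 1.2,
                          intensity_mixture = default_intensity_mixture(),
                          wbc_records_mean = 25) {
  intensity_mixture <- tibble::as_tibble(intensity_mixture)
  if (n_patients < 1) abort("n_patients must be >= 1")
  if (blood_volume_ml <= 0) abort("blood_volume_ml must be positive")
  if (ctc_rate_mean < 0 || ctc_rate_dispersion <= 0) {
    abort("ctc_rate_mean must be >= 0 and ctc_rate_dispersion > 0")
  }
  if (cluster_prob < 0 || cluster_prob > 1) abort("cluster_prob must be in [0, 1]")
  if (cluster_size_geom_prob <= 0 || cluster_size_geom_prob > 1) {
    abort("cluster_size_geom_prob must be in (0, 1]")
  }
  if (subtype_fraction < 0 || subtype_fraction > 1) abort("subtype_fraction must be in [0, 1]")
  if (abs(coupling_rho) > 1) abort("coupling_rho must be in [-1, 1]")
  if (!all(c("weight", "log_mean", "log_sd") %in% names(intensity_mixture))) {
    abort("intensity_mixture needs columns weight, log_mean, log_sd")
  }
  if (abs(sum(intensity_mixture$weight) - 1) > 1e-8) abort("mixture weights must sum to 1")
  if (any(intensity_mixture$log_sd <= 0)) abort("mixture log_sd values must be positive")
  structure(
    list(n_patients = as.integer(n_patients), seed = as.integer(seed),
         blood_volume_ml = blood_volume_ml,
         ctc_rate_mean = ctc_rate_mean,
         ctc_rate_dispersion = ctc_rate_dispersion,
         cluster_prob = cluster_prob,
         cluster_size_geom_prob = cluster_size_geom_prob,
         subtype_fraction = subtype_fraction,
         coupling_rho = coupling_rho,
         intensity_shift = intensity_shift,
         intensity_mixture = intensity_mixture,
         wbc_records_mean = wbc_records_mean),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_intensity_mixture <- function() {
  tibble::tibble(
    weight = c(0.5, 0.5),
    log_mean = c(log(1.5), log(12)),
    log_sd = c(0.8, 1.0)
  )
}

#' Read a cohort configuration from a YAML file
#'
#' Every field of [cohort_config()] may appear as a top-level key;
#' `intensity_mixture` as a list of `{weight, log_mean, log_sd}` maps.
#' Unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("unknown config key(s): ", paste(extra, collapse = ", ")))
  }
  if (!is.null(raw$intensity_mixture)) {
    raw$intensity_mixture <- purrr::map(raw$intensity_mixture, tibble::as_tibble) |>
      purrr::list_rbind()
  }
  do.call(cohort_config, raw)
}

# channel model shared by synthetic tumor-line cells, patient CTCs and
# WBC background records (fluorescence units)
channel_constants <- list(
  dapi_log_mean = log(100), dapi_log_sd = 0.3,
  ck_log_sd = 0.5,
  wbc_ck_level = 0.5, wbc_cd45_level = 50,
  wbc_t5t4_log_mean = log(0.3), wbc_t5t4_log_sd = 0.8,
  wbc_intact_prob = 0.95
)

tumor_cell_channels <- function(n, ck_level, cd45_level) {
  cc <- channel_constants
  tibble::tibble(
    dapi = rlnorm(n, cc$dapi_log_mean, cc$dapi_log_sd),
    ck = rlnorm(n, log(ck_level), cc$ck_log_sd),
    cd45 = if (cd45_level > 0) rlnorm(n, log(cd45_level), cc$ck_log_sd) else rep(0, n),
    intact_nucleus = rep(TRUE, n)
  )
}

wbc_records <- function(n, sample_id) {
  cc <- channel_constants
  tibble::tibble(
    sample_id = sample_id,
    cell_id = paste0(sample_id, "-w", seq_len(n)),
    cluster_id = NA_character_,
    dapi = rlnorm(n, cc$dapi_log_mean, cc$dapi_log_sd),
    ck = rlnorm(n, log(cc$wbc_ck_level), cc$ck_log_sd),
    cd45 = rlnorm(n, log(cc$wbc_cd45_level), cc$ck_log_sd),
    t5t4 = rlnorm(n, cc$wbc_t5t4_log_mean, cc$wbc_t5t4_log_sd),
    intact_nucleus = runif(n) < cc$wbc_intact_prob
  )
}

#' Simulate cells from a control line intensity profile
#'
#' Draws `n_cells` tumor-cell records whose 5T4 intensities are
#' log-normal with the profile's parameters; cytokeratin positive,
#' DAPI positive, CD45 at the profile's level (0 for tumor lines), all
#' nuclei intact.
#'
#' @param profile A one-row data frame (e.g. one row of
#'   [control_line_profiles()]) or list with `name`, `log_mean`,
#'   `log_sd`, `ck_level`, `cd45_level`.
#' @param n_cells Number of cells (>= 1).
#' @param seed Optional integer seed for a reproducible draw.
#' @return A per-cell tibble in the [simulate_cohort()] cells schema.
#' @examples
#' h226 <- control_line_profiles()[4, ]
#' cells <- simulate_line_cells(h226, 1000, seed = 1)
#' @export
simulate_line_cells <- function(profile, n_cells, seed = NULL) {
  profile <- as.list(profile)
  if (n_cells < 1) abort("n_cells must be >= 1")
  if (is.null(profile$log_sd) || profile$log_sd <= 0) abort("profile log_sd must be positive")
  if (is.null(profile$cd45_level) || profile$cd45_level < 0) abort("profile cd45_level must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sid <- paste0("line-", profile$name)
  ch <- tumor_cell_channels(n_cells, profile$ck_level, profile$cd45_level)
  tibble::tibble(
    sample_id = sid,
    cell_id = paste0(sid, "-c", seq_len(n_cells)),
    cluster_id = NA_character_,
    dapi = ch$dapi, ck = ch$ck, cd45 = ch$cd45,
    t5t4 = rlnorm(n_cells, profile$log_mean, profile$log_sd),
    intact_nucleus = ch$intact_nucleus
  )
}

#' Spike tumor cells into a white-blood-cell background
#'
#' Appends CD45+/CK- background records so that the expected
#' background-to-tumor ratio equals `wbc_per_tumor_cell` (the count is
#' Poisson), assigns every record the tumor cells' sample id, and
#' randomizes row order — emulating control samples prepared by
#' spiking cultured tumor cells into healthy donor blood (reference
#' density: 1 tumor cell per 10,000 WBCs).
#'
#' @param tumor_cells Non-empty per-cell tibble (single sample).
#' @param wbc_per_tumor_cell Expected WBCs per tumor cell (> 0, or 0
#'   for no background).
#' @param seed Optional integer seed.
#' @return A per-cell tibble containing the tumor cells and the
#'   background, shuffled.
#' @export
spike_into_background <- function(tumor_cells, wbc_per_tumor_cell, seed = NULL) {
  tumor_cells <- tibble::as_tibble(tumor_cells)
  if (nrow(tumor_cells) == 0) abort("tumor_cells must be non-empty")
  if (wbc_per_tumor_cell < 0) abort("wbc_per_tumor_cell must be >= 0")
  sid <- unique(tumor_cells$sample_id)
  if (length(sid) != 1) abort("tumor_cells must come from a single sample")
  if (!is.null(seed)) set.seed(seed)
  n_bg <- rpois(1, nrow(tumor_cells) * wbc_per_tumor_cell)
  out <- dplyr::bind_rows(tumor_cells, wbc_records(n_bg, sid))
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Monotone map from latent tumor expression to IHC membrane staining
#'
#' Converts latent tumor expression (standard-normal scale) into the
#' membrane-fraction triple scored by a pathologist: the total stained
#' fraction is `100 * pnorm(latent - 0.7)`, split 50/30/20 between
#' weak, moderate and strong. The resulting H-score
#' (`1.7 * 100 * pnorm(latent - 0.7)`, range 0-170) is strictly
#' increasing in the latent value, with a cohort mean near 52 matching
#' the reference cohort.
#'
#' @param latent Numeric vector of latent tumor expression values.
#' @return A tibble with `pct_weak`, `pct_moderate`, `pct_strong` and
#'   `ihc_h_score`.
#' @examples
#' latent_to_ihc(c(-1, 0, 1, 2))
#' @export
latent_to_ihc <- function(latent) {
  total <- 100 * pnorm(latent - 0.7)
  out <- tibble::tibble(
    pct_weak = 0.5 * total,
    pct_moderate = 0.3 * total,
    pct_strong = 0.2 * total
  )
  out$ihc_h_score <- ihc_h_score(out$pct_weak, out$pct_moderate, out$pct_strong)
  out
}

# partition n_clustered cells into cluster sizes >= 2; a leftover
# single cell is absorbed into the last cluster (or returned to the
# singleton pool when no cluster exists)
draw_cluster_sizes <- function(n_clustered, geom_prob) {
  sizes <- integer()
  rem <- n_clustered
  while (rem >= 2) {
    s <- min(2 + rgeom(1, geom_prob), rem)
    sizes <- c(sizes, s)
    rem <- rem - s
  }
  if (rem == 1) {
    if (length(sizes) > 0) sizes[length(sizes)] <- sizes[length(sizes)] + 1L else rem <- 1L
  }
  sizes
}

#' Simulate one patient's cells, record and ground truth
#'
#' Draws a latent (tumor, CTC) expression pair from a standard
#' bivariate normal with correlation `coupling_rho`, maps the tumor
#' side through [latent_to_ihc()], draws the CTC count, cluster
#' structure and per-cell intensities, and scores the generated cells
#' with the same pipeline used for real data ([score_sample()]).
#'
#' Uses the current RNG state; [simulate_cohort()] seeds once per run.
#'
#' @param config A [cohort_config()].
#' @param patient_index Integer used for the sample id.
#' @param subtype `"AC"` or `"SCC"` (cohort-level allocation).
#' @return A list with `cells` (per-cell tibble, CTCs plus WBC
#'   background), `patient` (one-row tibble: ids, subtype, stage,
#'   grade, `ihc_h_score` and the CTC metric panel) and `truth`
#'   (one-row tibble: latent values, true CTC count, cluster sizes).
#' @export
simulate_patient <- function(config, patient_index = 1, subtype = "AC") {
  sid <- sprintf("P%03d", patient_index)
  rho <- config$coupling_rho
  latent_tumor <- rnorm(1)
  latent_ctc <- rho * latent_tumor + sqrt(1 - rho^2) * rnorm(1)
  ihc <- latent_to_ihc(latent_tumor)

  stage <- sample(c("1A", "1B", "2A", "2B", "3A"), 1,
                  prob = c(0.35, 0.2, 0.2, 0.1, 0.15))
  grade <- sample(c("poorly differentiated", "moderately differentiated",
                    "well differentiated"), 1, prob = c(0.3, 0.5, 0.2))

  n_ctc <- rnbinom(1, mu = config$ctc_rate_mean * config$blood_volume_ml,
                   size = config$ctc_rate_dispersion)

  # cluster composition
  n_clustered <- rbinom(1, n_ctc, config$cluster_prob)
  sizes <- draw_cluster_sizes(n_clustered, config$cluster_size_geom_prob)
  n_in_clusters <- sum(sizes)
  n_single <- n_ctc - n_in_clusters
  cluster_labels <- if (length(sizes) > 0) {
    rep(paste0(sid, "-k", seq_along(sizes)), times = sizes)
  } else {
    character()
  }
  cluster_id <- c(rep(NA_character_, n_single), cluster_labels)

  mix <- config$intensity_mixture
  if (n_ctc > 0) {
    comp <- sample.int(nrow(mix), n_ctc, replace = TRUE, prob = mix$weight)
    t5t4 <- rlnorm(n_ctc,
                   mix$log_mean[comp] + config$intensity_shift * latent_ctc,
                   mix$log_sd[comp])
    ch <- tumor_cell_channels(n_ctc, ck_level = 50, cd45_level = 0)
    ctc_cells <- tibble::tibble(
      sample_id = sid,
      cell_id = paste0(sid, "-c", seq_len(n_ctc)),
      cluster_id = cluster_id,
      dapi = ch$dapi, ck = ch$ck, cd45 = ch$cd45,
      t5t4 = t5t4,
      intact_nucleus = ch$intact_nucleus
    )
  } else {
    ctc_cells <- wbc_records(0, sid)
  }
  n_wbc <- rpois(1, config$wbc_records_mean)
  cells <- dplyr::bind_rows(ctc_cells, wbc_records(n_wbc, sid))
  if (nrow(cells) > 0) cells <- cells[sample.int(nrow(cells)), , drop = FALSE]

  metrics <- if (nrow(cells) > 0) {
    score_sample(cells, volume_ml = config$blood_volume_ml)
  } else {
    score_sample(wbc_records(0, sid) |> dplyr::mutate(sample_id = sid),
                 volume_ml = config$blood_volume_ml) |>
      dplyr::mutate(sample_id = sid)
  }
  metrics$sample_id <- sid

  patient <- dplyr::bind_cols(
    tibble::tibble(sample_id = sid, subtype = subtype, stage = stage,
                   grade = grade, ihc_h_score = ihc$ihc_h_score),
    dplyr::select(metrics, -"sample_id")
  )
  truth <- tibble::tibble(
    sample_id = sid,
    latent_tumor = latent_tumor,
    latent_ctc = latent_ctc,
    n_ctc = as.integer(n_ctc),
    n_clusters = length(sizes),
    cluster_sizes = list(as.integer(sizes))
  )
  list(cells = cells, patient = patient, truth = truth)
}

#' Simulate a full patient cohort with known ground truth
#'
#' Seeds the generator once from `config$seed` and concatenates
#' [simulate_patient()] output for `n_patients` patients. Subtypes are
#' allocated deterministically: the first `round(n * subtype_fraction)`
#' patients are adenocarcinoma ("AC"), the rest squamous ("SCC").
#' Output is bit-identical for a fixed seed.
#'
#' @param config A [cohort_config()].
#' @return A list of class `ctc_cohort_sim` with three tibbles:
#'   `cohort` (one patient per row: subtype, stage, grade, tumor
#'   `ihc_h_score`, CTC metric panel), `cells` (per-cell records) and
#'   `truth` (latent values and true cluster structure), plus the
#'   `config` echoed.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_patients = 4, seed = 7))
#' sim$cohort
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  n_ac <- round(n * config$subtype_fraction)
  subtype <- c(rep("AC", n_ac), rep("SCC", n - n_ac))
  sims <- purrr::map(seq_len(n), \(i) simulate_patient(config, i, subtype[i]))
  structure(
    list(
      cohort = purrr::list_rbind(purrr::map(sims, "patient")),
      cells = purrr::list_rbind(purrr::map(sims, "cells")),
      truth = purrr::list_rbind(purrr::map(sims, "truth")),
      config = config
    ),
    class = "ctc_cohort_sim"
  )
}

#' Write the three cohort tables as delimited text
#'
#' Writes `cohort.csv`, `cells.csv` and `truth.csv` (comma separated,
#' header row, `NA` token, UTF-8) into `dir`; each file starts with a
#' `#`-comment header recording the generator seed. The truth table's
#' `cluster_sizes` list-column is serialized as a
#' semicolon-separated string.
#'
#' @param sim A `ctc_cohort_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "ctc_cohort_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- dplyr::mutate(
    sim$truth,
    cluster_sizes = purrr::map_chr(.data$cluster_sizes, paste, collapse = ";")
  )
  tabs <- list(cohort = sim$cohort, cells = sim$cells, truth = truth)
  paths <- purrr::imap_chr(tabs, function(tab, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# generator seed: ", sim$config$seed), con)
    utils::write.csv(tab, con, row.names = FALSE, na = "NA")
    path
  })
  invisible(paths)
}
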