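test_that("line cells honor the profile and are reproducible", {
  prof <- list(name = "flat", log_mean = log(10), log_sd = 1e-9,
               ck_level = 50, cd45_level = 0)
  cells <- simulate_line_cells(prof, 5, seed = 1)
  expect_equal(nrow(cells), 5)
  expect_equal(cells$t5t4, rep(10, 5), tolerance = 1e-6)
  expect_true(all(cells$cd45 == 0))
  expect_true(all(cells$intact_nucleus))

  again <- simulate_line_cells(prof, 5, seed = 1)
  expect_identical(cells, again)
  expect_error(simulate_line_cells(prof, 0), "n_cells")
  prof$log_sd <- -1
  expect_error(simulate_line_cells(prof, 5), "log_sd")
})

test_that("control line profiles are ordered by expected intensity", {
  p <- control_line_profiles()
  expected <- exp(p$log_mean + p$log_sd^2 / 2)
  expect_true(all(diff(expected) > 0))
  expect_equal(p$expression_class, c("negative", "low", "medium", "high"))
})

test_that("mid-expression control lines score near their reference H-scores", {
  p <- control_line_profiles()
  for (i in 2:3) {
    cells <- simulate_line_cells(p[i, ], 10000, seed = 100 + i)
    h <- h_score_from_categories(categorize_intensity(cells$t5t4))
    expect_lt(abs(h - p$reference_h_score[i]), 15)
  }
})

test_that("spiking adds CD45+ background at the configured Poisson rate", {
  tumor <- simulate_line_cells(control_line_profiles()[4, ], 3, seed = 2)
  spiked <- spike_into_background(tumor, wbc_per_tumor_cell = 100, seed = 3)
  n_bg <- sum(spiked$cd45 > 5)
  expect_lt(abs(n_bg - 300), 4 * sqrt(300))  # Poisson-consistent
  expect_equal(unique(spiked$sample_id), unique(tumor$sample_id))
  expect_setequal(spiked$cell_id[spiked$cd45 == 0], tumor$cell_id)

  # zero expected background: only the tumor cells, reshuffled
  none <- spike_into_background(tumor, 0, seed = 4)
  expect_setequal(none$cell_id, tumor$cell_id)

  # determinism
  expect_identical(spike_into_background(tumor, 50, seed = 9),
                   spike_into_background(tumor, 50, seed = 9))
  expect_error(spike_into_background(tumor, -1), ">= 0")
  expect_error(spike_into_background(tumor[0, ], 10), "non-empty")
})

test_that("cohort simulation is seed-deterministic with deterministic subtype split", {
  cfg <- cohort_config(n_patients = 35, seed = 77)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$cohort$subtype == "AC"), 25)
  expect_equal(sum(sim$cohort$subtype == "SCC"), 10)

  sim2 <- simulate_cohort(cfg)
  expect_identical(sim$cohort, sim2$cohort)
  expect_identical(sim$cells, sim2$cells)
  expect_identical(sim$truth, sim2$truth)

  other <- simulate_cohort(cohort_config(n_patients = 35, seed = 78))
  expect_false(identical(sim$cohort, other$cohort))

  # one patient: ids consistent across the three tables
  one <- simulate_cohort(cohort_config(n_patients = 1, seed = 5))
  expect_equal(unique(one$cells$sample_id), one$cohort$sample_id)
  expect_equal(one$truth$sample_id, one$cohort$sample_id)
})

test_that("generated data respects the model's structural invariants", {
  sim <- simulate_cohort(cohort_config(n_patients = 40, seed = 88))
  expect_true(all(sim$cells$t5t4 > 0))
  expect_true(all(sim$cells$dapi > 0))
  sizes <- unlist(sim$truth$cluster_sizes)
  if (length(sizes) > 0) expect_true(all(sizes >= 2))
  # per-patient: cluster cells + singles = true count
  expect_equal(purrr::map_int(sim$truth$cluster_sizes, sum) <= sim$truth$n_ctc,
               rep(TRUE, 40))
  # cohort metrics came from the same cells the table reports
  rescored <- score_cohort(sim$cells)
  expect_equal(rescored$ctc_h_score, sim$cohort$ctc_h_score)
  expect_equal(rescored$burden_per_ml, sim$cohort$burden_per_ml)
})

test_that("empirical mean CTC count matches the configured count law", {
  cfg <- cohort_config(n_patients = 2000, seed = 99, ctc_rate_mean = 12,
                       ctc_rate_dispersion = 0.6, wbc_records_mean = 0)
  sim <- simulate_cohort(cfg)
  mu <- 12
  se <- sqrt((mu + mu^2 / 0.6) / 2000)
  expect_lt(abs(mean(sim$truth$n_ctc) - mu), 3 * se)
  # gated counts agree with the ground truth
  expect_equal(sim$cohort$n_ctc, sim$truth$n_ctc)
})

test_that("a zero CTC rate yields empty metrics flagged NA", {
  cfg <- cohort_config(n_patients = 3, seed = 4, ctc_rate_mean = 0)
  sim <- simulate_cohort(cfg)
  expect_equal(sim$cohort$n_ctc, rep(0L, 3))
  expect_true(all(is.na(sim$cohort$ctc_h_score)))
  expect_true(all(is.na(sim$cohort$pct_negative)))
  expect_equal(sim$cohort$burden_per_ml, rep(0, 3))
})

test_that("the latent-to-IHC map is non-decreasing with valid membrane triples", {
  grid <- seq(-4, 4, by = 0.05)
  m <- latent_to_ihc(grid)
  expect_true(all(diff(m$ihc_h_score) >= 0))
  expect_true(all(m$pct_weak + m$pct_moderate + m$pct_strong <= 100 + 1e-9))
  expect_true(all(m$ihc_h_score >= 0 & m$ihc_h_score <= 300))
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(coupling_rho = 1.5), "coupling_rho")
  expect_error(cohort_config(cluster_prob = 2), "cluster_prob")
  bad_mix <- tibble::tibble(weight = c(0.7, 0.5), log_mean = c(0, 1), log_sd = c(1, 1))
  expect_error(cohort_config(intensity_mixture = bad_mix), "sum to 1")
  expect_error(cohort_config(ctc_rate_dispersion = 0), "dispersion")
})

test_that("YAML config and table writing round-trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 8", "seed: 11", "coupling_rho: 0.4",
               "cluster_prob: 0.2"), path)
  cfg <- read_cohort_config(path)
  expect_equal(cfg$n_patients, 8L)
  expect_equal(cfg$coupling_rho, 0.4)
  expect_error(read_cohort_config({
    p2 <- withr::local_tempfile(fileext = ".yaml")
    writeLines("not_a_field: 3", p2); p2
  }), "unknown config key")

  sim <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort_tables(sim, dir)
  expect_true(all(file.exists(paths)))
  cells <- utils::read.csv(paths[["cells"]], comment.char = "#")
  expect_setequal(unique(cells$sample_id), sim$cohort$sample_id)
  expect_equal(readLines(paths[["cohort"]], n = 1), "# generator seed: 11")
})
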