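test_that("the CTC gate is conjunctive and CD45 dominates", {
  gates <- gating_thresholds(ck_min = 5, cd45_max = 5, dapi_min = 5)
  cells <- tibble::tibble(
    sample_id = "s1",
    cell_id = paste0("c", 1:5),
    cluster_id = NA_character_,
    dapi = c(100, 100, 100, 100, 2),
    ck = c(40, 40, 0.2, 40, 40),
    cd45 = c(0, 60, 60, 0, 0),
    t5t4 = c(12, 12, 0.5, 12, 12),
    intact_nucleus = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  out <- classify_cells(cells, gates)
  expect_equal(out$label, c("CTC",
                            "WBC",    # CD45 high regardless of CK
                            "WBC",
                            "other",  # intact nucleus required
                            "other")) # DAPI below threshold
})

test_that("every cell gets exactly one label and 5T4 plays no role in identity", {
  set.seed(11)
  n <- 300
  cells <- tibble::tibble(
    sample_id = "s1", cell_id = paste0("c", 1:n), cluster_id = NA_character_,
    dapi = rlnorm(n, log(50), 1), ck = rlnorm(n, log(5), 1.5),
    cd45 = rlnorm(n, log(5), 1.5), t5t4 = rlnorm(n, 1, 1),
    intact_nucleus = runif(n) < 0.8
  )
  out <- classify_cells(cells)
  expect_true(all(out$label %in% c("CTC", "WBC", "other")))
  # shuffling the 5T4 channel changes nothing
  out2 <- classify_cells(dplyr::mutate(cells, t5t4 = sample(t5t4)))
  expect_identical(out$label, out2$label)
})

test_that("classification rejects negative intensities and missing columns", {
  bad <- tibble::tibble(sample_id = "s", cell_id = "c", dapi = -1, ck = 1,
                        cd45 = 1, t5t4 = 1, intact_nucleus = TRUE)
  expect_error(classify_cells(bad), "non-negative")
  expect_error(classify_cells(dplyr::select(bad, -dapi)), "lacks column")
})

test_that("entities group cluster members and conserve cells", {
  # three singletons
  singles <- make_ctc_cells(c(1, 5, 9))
  e <- assemble_entities(singles)
  expect_equal(nrow(e), 3)
  expect_equal(e$n_cells, rep(1L, 3))
  expect_equal(sort(e$entity_intensity), c(1, 5, 9))

  # a cluster's intensity is the arithmetic mean of its members
  clus <- make_ctc_cells(c(1, 1, 10), cluster_id = "k1")
  e2 <- assemble_entities(clus)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$n_cells, 3L)
  expect_equal(e2$entity_intensity, 4)

  # empty input
  expect_equal(nrow(assemble_entities(singles[0, ])), 0)

  # conservation on random mixed samples
  set.seed(21)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    cl <- sample(c(NA, "a", "b", "c"), n, replace = TRUE)
    cells <- make_ctc_cells(rlnorm(n, 1, 1), cluster_id = cl)
    ent <- assemble_entities(cells)
    expect_equal(sum(ent$n_cells), n)
    expect_true(all(ent$entity_intensity >= 0))
  }
})

test_that("a cluster id spanning two samples is rejected", {
  a <- make_ctc_cells(c(1, 2), cluster_id = "k1", sample_id = "s1")
  b <- make_ctc_cells(c(3, 4), cluster_id = "k1", sample_id = "s2")
  expect_error(assemble_entities(dplyr::bind_rows(a, b)), "across samples")
})

test_that("intensity categories use half-open bins at the printed boundaries", {
  x <- c(0, 2.99, 3, 7.99, 8, 19.99, 20, 1000)
  expect_equal(categorize_intensity(x), c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(categorize_intensity(-0.1), "non-negative")
  # a cutoff overrides the bins below it
  expect_equal(categorize_intensity(c(2, 5, 9), cutoff = 6), c(0L, 0L, 2L))
})

test_that("categorization is monotone and partitions the intensity axis", {
  set.seed(31)
  x <- sort(c(runif(200, 0, 30), c(3, 8, 20)))
  k <- categorize_intensity(x)
  expect_true(all(diff(k) >= 0))
  expect_true(all(k %in% 0:3))
})

test_that("the negativity cutoff is the negative line's mean intensity", {
  expect_equal(derive_negative_cutoff(data.frame(t5t4 = c(1, 2, 3))), 2)
  expect_equal(derive_negative_cutoff(c(0, 0, 0)), 0)
  expect_equal(derive_negative_cutoff(5), 5)
  expect_error(derive_negative_cutoff(numeric()), "no cells")
})
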