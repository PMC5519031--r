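test_that("the tissue H-score formula and its range checks", {
  expect_equal(ihc_h_score(0, 0, 0), 0)
  expect_equal(ihc_h_score(0, 0, 100), 300)
  expect_equal(ihc_h_score(30, 20, 10), 100)
  expect_equal(ihc_h_score(c(0, 30), c(0, 20), c(100, 10)), c(300, 100))
  expect_error(ihc_h_score(60, 30, 20), "sum")
  expect_error(ihc_h_score(-1, 0, 0), "0, 100")
})

test_that("category-percentage H-score matches a brute-force tabulation", {
  expect_equal(h_score_from_categories(c(0, 1, 2, 3)), 150)
  expect_equal(h_score_from_categories(rep(0L, 7)), 0)
  expect_equal(h_score_from_categories(rep(3L, 7)), 300)
  expect_true(is.na(h_score_from_categories(integer())))
  expect_true(is.na(h_score_from_categories(c(1, 2), weight = 0)))
  set.seed(41)
  for (i in 1:50) {
    k <- sample(0:3, sample(1:30, 1), replace = TRUE)
    counts <- vapply(0:3, function(j) sum(k == j), numeric(1))
    expected <- 100 * (counts[2] + 2 * counts[3] + 3 * counts[4]) / sum(counts)
    expect_equal(h_score_from_categories(k), expected)
  }
})

test_that("plain and cluster-weighted H-scores diverge only through clusters", {
  # one cluster {2.5, 2.5, 25}: entity mean 10 (medium) vs per-cell 0/0/high
  e <- assemble_entities(make_ctc_cells(c(2.5, 2.5, 25), cluster_id = "k1"))
  expect_equal(ctc_h_score(e), 200)
  expect_equal(cluster_weighted_h_score(e), 100)
  expect_true(is.na(ctc_h_score(e[0, ])))
  expect_true(is.na(cluster_weighted_h_score(e[0, ])))

  # cluster-free samples: all paired metrics identical
  set.seed(42)
  for (i in 1:20) {
    ent <- assemble_entities(make_ctc_cells(rlnorm(sample(1:30, 1), 1.5, 1.2)))
    expect_identical(ctc_h_score(ent), cluster_weighted_h_score(ent))
    expect_identical(burden_per_ml(ent), cluster_weighted_burden_per_ml(ent))
  }
})

test_that("burden sums raw intensity, includes 5T4-negative cells, scales with volume", {
  expect_equal(burden_per_ml(assemble_entities(make_ctc_cells(numeric())[0, ])), 0)
  two <- assemble_entities(make_ctc_cells(c(3, 4)))
  expect_equal(burden_per_ml(two, 1), 7)
  expect_equal(cluster_weighted_burden_per_ml(two, 1), 7)
  expect_equal(burden_per_ml(two, 2), 3.5)
  # all sub-cutoff cells: zero H-score but positive burden
  dim_cells <- assemble_entities(make_ctc_cells(c(1, 2, 2.5)))
  expect_equal(ctc_h_score(dim_cells, cutoff = 6), 0)
  expect_gt(burden_per_ml(dim_cells), 0)
  expect_error(burden_per_ml(two, 0), "positive")
})

test_that("CTC counts are cell-level (cluster members each count)", {
  cells <- dplyr::bind_rows(
    make_ctc_cells(c(1, 2, 3)),
    make_ctc_cells(c(5, 6), cluster_id = "k9")
  )
  cells$cell_id <- paste0("c", seq_len(nrow(cells)))
  ent <- assemble_entities(cells)
  expect_equal(ctc_per_ml(ent, 1), 5)
  expect_equal(ctc_per_ml(ent, 2), 2.5)
  expect_equal(ctc_per_ml(ent[0, ], 1), 0)
})

test_that("percent-negative counts member cells below the cutoff", {
  ent <- assemble_entities(make_ctc_cells(c(1, 2, 10, 30)))
  expect_equal(pct_negative_ctcs(ent, cutoff = 6), 50)
  expect_equal(pct_negative_ctcs(ent, cutoff = 0.5), 0)
  expect_equal(pct_negative_ctcs(ent, cutoff = 100), 100)
  expect_true(is.na(pct_negative_ctcs(ent[0, ])))
})

test_that("H-scores stay in [0, 300] and never decrease when a cell brightens", {
  set.seed(43)
  for (i in 1:25) {
    n <- sample(2:25, 1)
    cl <- sample(c(NA, "a", "b"), n, replace = TRUE)
    x <- rlnorm(n, 1.5, 1.3)
    ent <- assemble_entities(make_ctc_cells(x, cluster_id = cl))
    h1 <- ctc_h_score(ent); w1 <- cluster_weighted_h_score(ent)
    expect_true(h1 >= 0 && h1 <= 300)
    expect_true(w1 >= 0 && w1 <= 300)
    # brighten one random cell
    j <- sample(n, 1)
    x2 <- x; x2[j] <- x2[j] + runif(1, 0, 40)
    ent2 <- assemble_entities(make_ctc_cells(x2, cluster_id = cl))
    expect_gte(ctc_h_score(ent2), h1)
    expect_gte(cluster_weighted_h_score(ent2), w1)
  }
})

test_that("score_sample produces the full panel from raw records", {
  # one high cell in 1 mL
  one <- make_ctc_cells(25)
  row <- score_sample(one, volume_ml = 1)
  expect_equal(row$ctc_per_ml, 1)
  expect_equal(row$ctc_h_score, 300)
  expect_equal(row$burden_per_ml, 25)
  expect_equal(row$pct_negative, 0)

  # nothing passes the gate: zero counts, NA scores
  wbc <- tibble::tibble(sample_id = "s1", cell_id = "w1",
                        cluster_id = NA_character_, dapi = 100, ck = 0.3,
                        cd45 = 60, t5t4 = 0.2, intact_nucleus = TRUE)
  empty <- score_sample(wbc)
  expect_equal(empty$n_ctc, 0L)
  expect_equal(empty$ctc_per_ml, 0)
  expect_true(is.na(empty$ctc_h_score))
  expect_true(is.na(empty$pct_negative))
  expect_equal(empty$burden_per_ml, 0)

  expect_error(score_sample(dplyr::bind_rows(one, make_ctc_cells(1, sample_id = "s2"))),
               "single sample")
})

test_that("score_cohort scores each sample independently", {
  cells <- dplyr::bind_rows(
    make_ctc_cells(c(25, 25), sample_id = "a"),
    make_ctc_cells(c(1, 1, 1), sample_id = "b")
  )
  out <- score_cohort(cells)
  expect_equal(out$sample_id, c("a", "b"))
  expect_equal(out$ctc_per_ml, c(2, 3))
  expect_equal(out$ctc_h_score, c(300, 0))
})
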