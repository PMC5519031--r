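Package: ctcscore
Title: Circulating Tumor Cell 5T4 Scoring and Tumor Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies 5T4 (trophoblast glycoprotein) expression in
    circulating tumor cells (CTCs) from per-cell immunofluorescence
    intensity records and relates it to matched tumor-tissue
    immunohistochemistry. Implements CD45-/CK+/DAPI+ cell gating,
    negative/low/medium/high intensity categorization, CTC H-scores
    (plain and cluster-weighted), 5T4 burden per mL, tumor IHC
    H-scoring, Spearman rank concordance with exact permutation
    p-values, nonparametric group comparisons, and a seeded synthetic
    cohort generator with known ground truth for validating the whole
    pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
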