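#' Nonparametric and parametric group comparisons
#'
#' Thin wrappers around the standard tests, with the degenerate-input
#' convention used throughout the package: when every observation in
#' every group is identical the comparison is uninformative and the
#' p-value is reported as 1.
#'
#' * `mann_whitney(x, y)` — two-sided Mann-Whitney U (Wilcoxon rank
#'   sum); exact when both groups have at most 8 observations and there
#'   are no ties, otherwise the normal approximation with tie
#'   correction.
#' * `kruskal_wallis(groups)` — Kruskal-Wallis H with tie correction,
#'   chi-square p-value.
#' * `one_way_anova(groups)` — one-way ANOVA F test.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param groups A named or unnamed list of numeric vectors, each
#'   non-empty; at least 2 groups.
#' @return An object of class `ctc_group_test`: list with `test`,
#'   `statistic`, `p_value`, `group_ns`. `tidy()` returns a one-row
#'   tibble.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @name group_tests
NULL

group_test <- function(test, statistic, p_value, group_ns) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = p_value, group_ns = group_ns),
            class = "ctc_group_test")
}

all_identical <- function(values) {
  length(unique(unlist(values, use.names = FALSE))) == 1
}

#' @rdname group_tests
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  if (all_identical(list(x, y))) {
    return(group_test("mann_whitney", length(x) * length(y) / 2, 1,
                      c(length(x), length(y))))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- length(x) <= 8 && length(y) <= 8 && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)
  )
  group_test("mann_whitney", res$statistic, res$p.value,
             c(length(x), length(y)))
}

#' @rdname group_tests
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  if (all_identical(groups)) {
    return(group_test("kruskal_wallis", 0, 1, lengths(groups)))
  }
  res <- stats::kruskal.test(groups)
  group_test("kruskal_wallis", res$statistic, res$p.value, lengths(groups))
}

#' @rdname group_tests
#' @export
one_way_anova <- function(groups) {
  check_groups(groups)
  if (all_identical(groups)) {
    return(group_test("anova", 0, 1, lengths(groups)))
  }
  value <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::aov(value ~ g)
  tab <- summary(fit)[[1]]
  group_test("anova", tab$`F value`[1], tab$`Pr(>F)`[1], lengths(groups))
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) abort("need a list of at least 2 groups")
  if (any(lengths(groups) == 0)) abort("every group must be non-empty")
  invisible(groups)
}

#' @export
print.ctc_group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-sided p = %.4g (n = %s)\n",
              x$test, x$statistic, x$p_value,
              paste(x$group_ns, collapse = ", ")))
  invisible(x)
}

#' @rdname group_tests
#' @param ... Unused.
#' @export
tidy.ctc_group_test <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic,
                 p.value = x$p_value,
                 n = list(as.integer(x$group_ns)))
}

#' Compare a metric between groups of a cohort table
#'
#' Tidy-eval convenience wrapper: splits `value` by `group` and runs
#' one of the [group_tests]. Rows with a missing value are dropped.
#'
#' @param data A data frame.
#' @param value,group Columns of `data` (unquoted).
#' @param test One of `"mann_whitney"`, `"kruskal_wallis"`, `"anova"`.
#'   `"mann_whitney"` requires exactly two groups.
#' @return A `ctc_group_test` object.
#' @examples
#' cohort <- fixture_patient_cohort()
#' compare_groups(cohort, ihc_h_score, subtype, "mann_whitney")
#' @export
compare_groups <- function(data, value, group,
                           test = c("mann_whitney", "kruskal_wallis", "anova")) {
  test <- match.arg(test)
  v <- eval_tidy(enquo(value), data)
  g <- eval_tidy(enquo(group), data)
  keep <- !is.na(v) & !is.na(g)
  groups <- split(v[keep], g[keep])
  if (test == "mann_whitney") {
    if (length(groups) != 2) abort("mann_whitney requires exactly 2 groups")
    mann_whitney(groups[[1]], groups[[2]])
  } else if (test == "kruskal_wallis") {
    kruskal_wallis(groups)
  } else {
    one_way_anova(groups)
  }
}

#' Mean and standard error of the mean
#'
#' @param x Numeric vector; missing values are dropped.
#' @return A one-row tibble with `n`, `mean` and `sem` (sample standard
#'   deviation over `sqrt(n)`; `NA` when `n < 2`).
#' @examples
#' mean_sem(fixture_patient_cohort()$ihc_h_score)
#' @export
mean_sem <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) abort("no non-missing values")
  tibble::tibble(n = n, mean = mean(x),
                 sem = if (n >= 2) stats::sd(x) / sqrt(n) else NA_real_)
}

#' Tumor / CTC positivity concordance counts
#'
#' Counts, over a cohort table carrying both compartments, how many
#' patients are 5T4 positive in the tumor (default: IHC H-score > 0),
#' how many of those are also positive in the CTC compartment (default:
#' CTC H-score > 0), and how many are CTC positive without tumor
#' positivity. A missing CTC H-score (no CTCs detected) counts as not
#' CTC-positive.
#'
#' @param cohort A cohort table (see [fixture_patient_cohort()] for the
#'   column set).
#' @param tumor,ctc Positivity rules as unquoted logical expressions in
#'   the cohort's columns.
#' @return A one-row tibble: `n_total`, `n_tumor_pos`, `n_both_pos`,
#'   `n_ctc_only`, plus the derived percentages `pct_tumor_pos` (of
#'   all), `pct_both_pos` (of tumor-positive) and `pct_ctc_only` (of
#'   all).
#' @examples
#' concordance_counts(fixture_patient_cohort())
#' @export
concordance_counts <- function(cohort,
                               tumor = .data$ihc_h_score > 0,
                               ctc = .data$ctc_h_score > 0) {
  tpos <- eval_tidy(enquo(tumor), cohort)
  cpos <- eval_tidy(enquo(ctc), cohort)
  tpos[is.na(tpos)] <- FALSE
  cpos[is.na(cpos)] <- FALSE
  n_total <- nrow(cohort)
  n_tumor_pos <- sum(tpos)
  n_both_pos <- sum(tpos & cpos)
  n_ctc_only <- sum(cpos & !tpos)
  tibble::tibble(
    n_total = n_total,
    n_tumor_pos = n_tumor_pos,
    n_both_pos = n_both_pos,
    n_ctc_only = n_ctc_only,
    pct_tumor_pos = 100 * n_tumor_pos / n_total,
    pct_both_pos = if (n_tumor_pos > 0) 100 * n_both_pos / n_tumor_pos else NA_real_,
    pct_ctc_only = 100 * n_ctc_only / n_total
  )
}
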