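#' Mid-ranks of a numeric vector
#'
#' Ranks 1..n with tied values receiving the average of the rank
#' positions they occupy. Mid-ranks always sum to `n * (n + 1) / 2`.
#'
#' @param x Numeric vector without missing values.
#' @return Numeric vector of ranks.
#' @examples
#' midrank(c(0, 0, 30, 30, 35))  # 1.5 1.5 3.5 3.5 5
#' @export
midrank <- function(x) {
  if (length(x) == 0) abort("empty input")
  if (any(is.na(x))) abort("missing values are not allowed; remove pairs first")
  rank(x, ties.method = "average")
}

#' Spearman rank correlation, classical uncorrected formula
#'
#' Computes `rho = 1 - 6 * sum(d^2) / (n * (n^2 - 1))` where `d` is the
#' difference of mid-ranks of `x` and `y`. With ties present this
#' "uncorrected" convention differs from Pearson correlation of the
#' ranks; it is the convention of the reference analyses this package
#' reproduces, and it is what common spreadsheet/BI tools report. The
#' tie-variance-corrected variant (Pearson on mid-ranks) is available
#' with `tie_correction = TRUE`.
#'
#' Pairs with a missing value in either member are dropped before
#' ranking (pairwise deletion).
#'
#' @param x,y Equal-length numeric vectors; at least 3 complete pairs.
#' @param tie_correction Use Pearson correlation of mid-ranks instead
#'   of the classical formula.
#' @return A single correlation in `[-1, 1]`, or `NA` if either margin
#'   is constant after pair deletion.
#' @examples
#' spearman_rho(1:10, (1:10)^3)  # 1: monotone invariance
#' @export
spearman_rho <- function(x, y, tie_correction = FALSE) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) return(NA_real_)
  rx <- midrank(x); ry <- midrank(y)
  if (tie_correction) {
    return(stats::cor(rx, ry))
  }
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# all permutations of 1..n as an n! x n matrix, cached
perm_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  P <- matrix(1L, 1, 1)
  if (n > 1) {
    for (m in 2:n) {
      # insert m at each position of every permutation of 1..(m-1)
      blocks <- lapply(seq_len(m), function(pos) {
        cbind(P[, seq_len(pos - 1), drop = FALSE],
              m,
              P[, seq(pos, m - 1)[seq_len(m - pos)], drop = FALSE])
      })
      P <- do.call(rbind, blocks)
    }
  }
  storage.mode(P) <- "integer"
  .perm_cache[[key]] <- P
  P
}

#' Spearman correlation test with exact permutation p-value
#'
#' Two-sided test of rank association using the classical uncorrected
#' rho of [spearman_rho()]. For small samples (`n <= exact_n_max`,
#' default 9) the p-value is exact: the fraction of all `n!` rank
#' permutations whose `|rho|` is at least the observed `|rho|`
#' (including the observed arrangement, so `p > 0` always). For larger
#' samples the usual t approximation is used:
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of
#' freedom. When `|rho| = 1` under the approximation the p-value is
#' reported as the smallest positive double rather than 0.
#'
#' @inheritParams spearman_rho
#' @param exact_n_max Largest n for which the exact permutation
#'   distribution is enumerated.
#' @return An object of class `ctc_spearman`: a list with `rho`, `n`,
#'   `p_value`, `method` (`"exact_permutation"` or
#'   `"t_approximation"`) and `tie_correction`. [tidy()] and
#'   [glance()] methods return one-row tibbles.
#' @examples
#' st <- spearman_test(c(1, 2, 3, 4), c(2, 1, 3, 4))
#' tidy(st)
#' @export
spearman_test <- function(x, y, exact_n_max = 9, tie_correction = FALSE) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  rho <- spearman_rho(x, y, tie_correction = tie_correction)
  if (is.na(rho)) {
    out <- list(rho = NA_real_, n = n, p_value = NA_real_,
                method = "undefined", tie_correction = tie_correction)
    return(structure(out, class = "ctc_spearman"))
  }
  if (n <= exact_n_max) {
    rx <- midrank(x); ry <- midrank(y)
    P <- perm_matrix(n)
    if (tie_correction) {
      M <- matrix(rx[P], nrow = nrow(P))
      rhos <- apply(M, 1, function(r) stats::cor(r, ry))
    } else {
      D2 <- rowSums((matrix(rx[P], nrow = nrow(P)) -
                       matrix(ry, nrow(P), n, byrow = TRUE))^2)
      rhos <- 1 - 6 * D2 / (n * (n^2 - 1))
    }
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    if (p <= 0) p <- .Machine$double.xmin
    method <- "t_approximation"
  }
  structure(list(rho = rho, n = n, p_value = p, method = method,
                 tie_correction = tie_correction),
            class = "ctc_spearman")
}

#' @export
print.ctc_spearman <- function(x, ...) {
  cat("Spearman rank correlation (", x$method, ")\n", sep = "")
  cat(sprintf("  rho = %.4f, n = %d, two-sided p = %.4g\n",
              x$rho, x$n, x$p_value))
  invisible(x)
}

#' @rdname spearman_test
#' @param x A `ctc_spearman` object.
#' @param ... Unused.
#' @export
tidy.ctc_spearman <- function(x, ...) {
  tibble::tibble(estimate = x$rho, statistic = x$rho, p.value = x$p_value,
                 method = x$method, n = x$n)
}

#' @rdname spearman_test
#' @export
glance.ctc_spearman <- function(x, ...) {
  tibble::tibble(rho = x$rho, n = x$n, p.value = x$p_value,
                 method = x$method, tie_correction = x$tie_correction)
}
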