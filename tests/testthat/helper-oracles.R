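# Independent oracles used to cross-check package computations.
# Deliberately written without calling package internals: ranks are
# computed from sort order, permutations enumerated recursively, and
# the generative model re-simulated in plain R.

# mid-ranks from scratch (average of occupied positions)
oracle_midrank <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  pos <- 1
  while (pos <= n) {
    run <- pos
    while (run < n && x[ord[run + 1]] == x[ord[pos]]) run <- run + 1
    r[ord[pos:run]] <- mean(pos:run)
    pos <- run + 1
  }
  r
}

oracle_rho <- function(x, y) {
  n <- length(x)
  d <- oracle_midrank(x) - oracle_midrank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# all permutations of 1..n, recursive construction
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- oracle_perms(n - 1)
  out <- list()
  for (p in smaller) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# exact two-sided permutation p by full enumeration
oracle_exact_p <- function(x, y) {
  rx <- oracle_midrank(x)
  ry <- oracle_midrank(y)
  n <- length(x)
  obs <- oracle_rho(x, y)
  rhos <- vapply(oracle_perms(n), function(p) {
    d <- rx[p] - ry
    1 - 6 * sum(d^2) / (n * (n^2 - 1))
  }, numeric(1))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Direct plain-R simulation of the synthetic cohort's generative model
# (latent bivariate pair -> monotone maps -> NB count -> cluster
# structure -> per-cell mixture intensities -> entity-level H-score),
# mirroring the default cohort_config() study conditions. Returns the
# per-cohort Spearman rho between tumor H-score and CTC H-score.
oracle_model_rho <- function(coupling_rho, n_patients = 35,
                             nb_mean = 48, nb_size = 0.6,
                             cluster_prob = 0.3, geom_prob = 0.5,
                             shift = 1.2) {
  cutoff <- exp(1.321927 + 0.5)
  categorize <- function(x) {
    k <- findInterval(x, c(3, 8, 20))
    k[x < cutoff] <- 0
    k
  }
  tum <- rnorm(n_patients)
  ctc <- coupling_rho * tum + sqrt(1 - coupling_rho^2) * rnorm(n_patients)
  ihc <- 170 * pnorm(tum - 0.7)
  h <- rep(NA_real_, n_patients)
  for (i in seq_len(n_patients)) {
    m <- rnbinom(1, mu = nb_mean, size = nb_size)
    if (m == 0) next
    comp <- runif(m) < 0.5
    x <- rlnorm(m, ifelse(comp, log(1.5), log(12)) + shift * ctc[i],
                ifelse(comp, 0.8, 1.0))
    # cluster composition: entity intensities are cluster means
    n_cl <- rbinom(1, m, cluster_prob)
    sizes <- integer(); rem <- n_cl
    while (rem >= 2) {
      s <- min(2 + rgeom(1, geom_prob), rem)
      sizes <- c(sizes, s); rem <- rem - s
    }
    if (rem == 1 && length(sizes) > 0) sizes[length(sizes)] <- sizes[length(sizes)] + 1
    n_in <- sum(sizes)
    ent <- x[seq_len(m - n_in)]               # singletons
    idx <- m - n_in
    for (s in sizes) { ent <- c(ent, mean(x[idx + seq_len(s)])); idx <- idx + s }
    h[i] <- 100 * mean(categorize(ent))
  }
  ok <- !is.na(h)
  if (sum(ok) < 3) return(NA_real_)
  rx <- oracle_midrank(ihc[ok]); ry <- oracle_midrank(h[ok])
  n <- sum(ok)
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# quick builder for gate-passing CTC records
make_ctc_cells <- function(t5t4, cluster_id = NA_character_, sample_id = "s1") {
  tibble::tibble(
    sample_id = sample_id,
    cell_id = paste0(sample_id, "-c", seq_along(t5t4)),
    cluster_id = rep_len(cluster_id, length(t5t4)),
    dapi = 100, ck = 50, cd45 = 0,
    t5t4 = t5t4,
    intact_nucleus = TRUE
  )
}
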