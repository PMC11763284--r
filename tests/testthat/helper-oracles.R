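# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the vectorized code paths they check.

# pair-counting Rand/adjusted Rand: enumerate all unordered pairs.
ari_pair_counting <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (!same_a && !same_b) s00 <- s00 + 1
      else if (same_a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  np <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / np
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == expected) return(1)
  (s11 - expected) / (max_idx - expected)
}

# naive triple-loop imputation (weighted or unweighted)
impute_triple_loop <- function(values, weights, epsilon, weighted = TRUE) {
  out <- values
  n_genes <- nrow(values)
  n_cells <- ncol(values)
  for (i in seq_len(n_cells)) {
    for (j in seq_len(n_genes)) {
      if (values[j, i] != 0) next
      num <- 0
      den <- 0
      for (k in seq_len(n_cells)) {
        if (k == i) next
        w <- weights[i, k]
        if (w == 0) next
        if (!weighted) w <- 1
        num <- num + w * values[j, k]
        den <- den + w
      }
      out[j, i] <- num / (den + epsilon)
    }
  }
  out
}

# two separable Gaussian blobs in gene space: gene x cell matrix plus labels
make_blobs <- function(n_genes = 30, cells_per_blob = 30, sep = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * cells_per_blob
  shift <- c(rep(0, cells_per_blob), rep(sep, cells_per_blob))
  m <- matrix(rnorm(n_genes * n), n_genes, n) +
    matrix(shift, n_genes, n, byrow = TRUE) * rep(c(1, -1), length.out = n_genes)
  dimnames(m) <- list(sprintf("Gene%d", 1:n_genes), sprintf("Cell%d", 1:n))
  list(mat = m, labels = rep(1:2, each = cells_per_blob))
}

# small simulated dataset for pipeline tests
small_sim <- function(seed = 1, de_fac_loc = 0.3, dropout_mid = 2,
                      cells_per_group = 100, n_genes = 120) {
  splat_simulate(sim_params(seed = seed, de_fac_loc = de_fac_loc,
                            dropout_mid = dropout_mid,
                            cells_per_group = cells_per_group,
                            n_genes = n_genes))
}
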