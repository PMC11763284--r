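make_weights <- function(m, c = 0.2) neighbor_weights(m, c)

test_that("neighbor_weights applies the cutoff and zeroes the self-weight", {
  cons <- matrix(c(1, 0.6, 0.1,
                   0.6, 1, 0.3,
                   0.1, 0.3, 1), 3, 3)
  w <- neighbor_weights(cons, c = 0.2)
  expect_equal(w$weights[1, ], c(0, 0.6, 0))
  expect_equal(diag(w$weights), rep(0, 3))
  # c = 0 keeps all off-diagonal entries
  w0 <- neighbor_weights(cons, c = 0)
  expect_equal(w0$weights[1, 3], 0.1)
  # c = 1 keeps only always-co-clustered pairs
  w1 <- neighbor_weights(matrix(c(1, 1, 0.9, 1, 1, 0.5, 0.9, 0.5, 1), 3, 3), c = 1)
  expect_equal(w1$weights[1, 2], 1)
  expect_equal(w1$weights[1, 3], 0)
  expect_error(neighbor_weights(cons, c = 2), "\\[0, 1\\]")
})

test_that("weighted and unweighted estimates match hand arithmetic", {
  # cell 1 has a zero at the only gene; neighbors hold 4 and 1
  values <- matrix(c(0, 4, 1), 1, 3,
                   dimnames = list("G1", c("C1", "C2", "C3")))
  w <- matrix(c(1, 0.5, 1.0,
                0.5, 1, 0.2,
                1.0, 0.2, 1), 3, 3)
  nw <- neighbor_weights(w, c = 0.1)
  wt <- impute_weighted(values, nw, epsilon = 0.01)
  expect_equal(wt$values[1, 1], (0.5 * 4 + 1 * 1) / (1.5 + 0.01), tolerance = 1e-12)
  uw <- impute_unweighted(values, nw, epsilon = 0.01)
  expect_equal(uw$values[1, 1], (4 + 1) / (2 + 0.01), tolerance = 1e-12)
  # single neighbor with value v imputes to v / (1 + eps)
  nw1 <- neighbor_weights(matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3), c = 0.5)
  one <- impute_unweighted(matrix(c(0, 7, 3), 1, 3), nw1, epsilon = 0.01)
  expect_equal(one$values[1, 1], 7 / 1.01, tolerance = 1e-12)
})

test_that("equal weights make weighted and unweighted estimates agree", {
  set.seed(1)
  values <- matrix(rpois(30, 3), 5, 6) * matrix(rbinom(30, 1, 0.6), 5, 6)
  w <- matrix(0.7, 6, 6)
  nw <- neighbor_weights(w, c = 0.2)
  a <- impute_weighted(values, nw, epsilon = 1e-9)$values
  b <- impute_unweighted(values, nw, epsilon = 1e-9)$values
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("nonzero entries pass through bit-exactly; mask matches zeros", {
  sim <- small_sim(seed = 21, cells_per_group = 40, n_genes = 60)
  norm <- log_normalize(sim$counts_dropout)
  set.seed(2)
  cons <- matrix(runif(6400), 80, 80)
  cons <- (cons + t(cons)) / 2
  diag(cons) <- 1
  nw <- neighbor_weights(cons, 0.2)
  imp <- impute_weighted(norm, nw)
  nz <- norm$values != 0
  expect_identical(imp$values[nz], norm$values[nz])
  expect_identical(imp$imputed_mask, norm$values == 0)
  expect_equal(sum(imp$imputed_mask), sum(norm$values == 0))
})

test_that("neighborless cells and all-zero genes stay zero", {
  values <- matrix(c(0, 5, 2,
                     0, 0, 0), 2, 3, byrow = TRUE)
  w <- matrix(0, 3, 3)
  diag(w) <- 1
  nw <- neighbor_weights(w, c = 0.2)  # no neighbors survive
  imp <- impute_weighted(values, nw)
  expect_true(all(imp$values[1, 1] == 0))
  expect_true(all(imp$values[2, ] == 0))
  # with neighbors, an all-zero gene still imputes to zero
  w2 <- matrix(0.9, 3, 3)
  imp2 <- impute_weighted(values, neighbor_weights(w2, 0.2))
  expect_true(all(imp2$values[2, ] == 0))
})

test_that("imputed values are bounded by the neighbor maximum", {
  set.seed(3)
  values <- matrix(rexp(200), 10, 20) * matrix(rbinom(200, 1, 0.5), 10, 20)
  cons <- matrix(runif(400, 0.1, 1), 20, 20)
  cons <- (cons + t(cons)) / 2
  diag(cons) <- 1
  nw <- neighbor_weights(cons, 0.3)
  imp <- impute_weighted(values, nw)
  for (g in 1:10) {
    expect_true(all(imp$values[g, ] >= 0))
    expect_true(all(imp$values[g, imp$imputed_mask[g, ]] <= max(values[g, ]) + 1e-12))
  }
})

test_that("epsilon -> 0 converges to the weighted mean with >= 1 neighbor", {
  values <- matrix(c(0, 2, 6), 1, 3)
  w <- matrix(c(1, 0.4, 0.6, 0.4, 1, 0.2, 0.6, 0.2, 1), 3, 3)
  nw <- neighbor_weights(w, 0.1)
  exact <- (0.4 * 2 + 0.6 * 6) / (0.4 + 0.6)
  for (eps in c(1e-2, 1e-8)) {
    got <- impute_weighted(values, nw, epsilon = eps)$values[1, 1]
    expect_equal(got, exact, tolerance = 2 * eps)
  }
})

test_that("vectorized imputation equals the triple-loop oracle", {
  set.seed(4)
  values <- matrix(rpois(600, 2), 30, 20) * matrix(rbinom(600, 1, 0.6), 30, 20)
  cons <- matrix(runif(400), 20, 20)
  cons <- (cons + t(cons)) / 2
  diag(cons) <- 1
  nw <- neighbor_weights(cons, 0.3)
  eps <- 1e-6
  expect_equal(impute_weighted(values, nw, eps)$values,
               impute_triple_loop(values, nw$weights, eps, weighted = TRUE),
               tolerance = 1e-10)
  expect_equal(impute_unweighted(values, nw, eps)$values,
               impute_triple_loop(values, nw$weights, eps, weighted = FALSE),
               tolerance = 1e-10)
})

test_that("cci_run leaves a zero-free matrix unchanged and reports metadata", {
  set.seed(5)
  counts <- matrix(rpois(60 * 50, 8) + 1, 60, 50)
  run <- cci_run(counts, cci_params(m = 2, gene_pool = 30, seed = 1,
                                    umap_epochs = 50))
  expect_identical(run$imputed$values, run$norm$values)
  expect_equal(run$meta$n_imputed, 0)
  expect_equal(run$meta$n_cells, 50)
})

test_that("imputation improves Spearman recovery on strong-signal data", {
  better <- vapply(1:3, function(s) {
    sim <- splat_simulate(sim_params(seed = s, de_fac_loc = 0.3, dropout_mid = 4,
                                     cells_per_group = 100, n_genes = 150))
    norm_true <- log_normalize(sim$counts)
    norm_drop <- log_normalize(sim$counts_dropout)
    run <- cci_run(norm_drop, cci_params(m = 10, seed = s, umap_epochs = 100))
    sp_drop <- gene_recovery_correlation(norm_drop, norm_true, sim$true_de_genes)
    sp_imp <- gene_recovery_correlation(run$imputed, norm_true, sim$true_de_genes)
    as.numeric(sp_imp) - as.numeric(sp_drop)
  }, numeric(1))
  expect_gt(mean(better), 0)
})
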