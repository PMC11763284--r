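test_that("adjusted_rand_index matches the pair-counting oracle", {
  set.seed(1)
  for (i in 1:5) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_pair_counting(a, b),
                 tolerance = 1e-12)
  }
  # contingency [[2,1],[1,2]] on 6 items
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)
  expect_equal(adjusted_rand_index(a, b), ari_pair_counting(a, b))
  # identity, relabeling invariance
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, c(9, 9, 9, 4, 4, 4)), 1)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("adjusted_rand_index agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(2)
  for (i in 1:5) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- sample(1:3, 50, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("random independent labels give near-zero ARI", {
  set.seed(3)
  vals <- replicate(20, adjusted_rand_index(sample(1:2, 200, replace = TRUE),
                                            sample(1:2, 200, replace = TRUE)))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("compactness satisfies the ANOVA decomposition and its bounds", {
  set.seed(4)
  pts <- matrix(rnorm(200), 100, 2)
  labels <- sample(1:3, 100, replace = TRUE)
  cmp <- compactness(pts, labels)
  expect_true(cmp >= 0 && cmp <= 1)
  # B + W = total sum of squares about the grand mean
  grand <- colMeans(pts)
  tss <- sum(sweep(pts, 2, grand)^2)
  B <- sum(sapply(unique(labels), function(k) {
    idx <- labels == k
    sum(idx) * sum((colMeans(pts[idx, , drop = FALSE]) - grand)^2)
  }))
  W <- sum(sapply(unique(labels), function(k) {
    idx <- labels == k
    sum(sweep(pts[idx, , drop = FALSE], 2, colMeans(pts[idx, , drop = FALSE]))^2)
  }))
  expect_equal(B + W, tss, tolerance = 1e-8)
  expect_equal(cmp, B / tss, tolerance = 1e-12)
  # zero within-variance: compactness 1
  tight <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  expect_equal(compactness(tight, rep(1:2, each = 10)), 1)
  # random labels on one Gaussian cloud: near zero
  expect_lt(compactness(pts, sample(1:2, 100, replace = TRUE)), 0.05)
  expect_warning(res <- compactness(pts, rep(1, 100)), "single cluster")
  expect_equal(res, 0)
})

test_that("vectorized Wilcoxon p-values match stats::wilcox.test", {
  set.seed(5)
  x <- matrix(rpois(25 * 40, 2), 25, 40,
              dimnames = list(sprintf("G%d", 1:25), NULL))
  labels <- rep(1:2, each = 20)
  x[1:5, labels == 1] <- x[1:5, labels == 1] + 3  # shifted genes
  de <- wilcoxon_de(x, labels, adjust = "bonferroni")
  ref <- apply(x, 1, function(v)
    stats::wilcox.test(v[labels == 1], v[labels == 2], exact = FALSE,
                       correct = TRUE)$p.value)
  expect_equal(de$table$p, unname(ref), tolerance = 1e-10)
})

test_that("wilcoxon_de declaration rules behave at the edges", {
  set.seed(6)
  x <- matrix(rpois(20 * 30, 3), 20, 30,
              dimnames = list(sprintf("G%d", 1:20), NULL))
  x[7, ] <- 0  # all-zero gene
  labels <- rep(1:2, each = 15)
  de <- wilcoxon_de(x, labels)
  expect_false("G7" %in% de$declared)
  # infinite fold-change threshold declares nothing
  de_inf <- wilcoxon_de(x, labels, lfc_min = Inf)
  expect_length(de_inf$declared, 0)
  # three clusters: largest two used, with a message
  lab3 <- c(rep(1, 14), rep(2, 12), rep(3, 4))
  expect_message(wilcoxon_de(x, lab3), "largest two")
  expect_error(wilcoxon_de(x, c(rep(1, 28), rep(2, 2))), "fewer than 3")
})

test_that("wilcoxon DE is calibrated under the null", {
  # de_prob = 0: groups exchangeable; raw p < alpha should fire at ~alpha,
  # and the Bonferroni-declared set should be (near) empty
  fpr <- vapply(1:5, function(s) {
    sim <- splat_simulate(sim_params(seed = s, de_prob = 0, dropout_mid = -10,
                                     cells_per_group = 60, n_genes = 150))
    norm <- log_normalize(sim$counts)
    de <- wilcoxon_de(norm, sim$group_labels)
    c(mean(de$table$p < 0.05), length(de$declared))
  }, numeric(2))
  expect_lt(abs(mean(fpr[1, ]) - 0.05), 0.03)
  expect_lt(mean(fpr[2, ]), 2)
})

test_that("set_metrics computes Jaccard, sensitivity, specificity", {
  uni <- sprintf("G%d", 1:500)
  truth <- uni[1:103]
  declared <- c(uni[1:55], uni[104:113])  # 55 true, 10 false
  sm <- set_metrics(declared, truth, uni)
  # |A∪B| = 65 + 103 - 55 = 113
  expect_equal(sm$jaccard, 55 / 113)
  expect_equal(sm$sensitivity, 55 / 103)
  expect_equal(sm$specificity, 387 / 397)
  # identical nonempty sets
  sm1 <- set_metrics(truth, truth, uni)
  expect_equal(unlist(sm1), c(jaccard = 1, sensitivity = 1, specificity = 1))
  # disjoint sets
  sm0 <- set_metrics(uni[201:210], truth, uni)
  expect_equal(sm0$jaccard, 0)
  expect_equal(sm0$sensitivity, 0)
  # empty truth: sensitivity undefined
  sme <- set_metrics(uni[1:3], character(0), uni)
  expect_true(is.na(sme$sensitivity))
  expect_error(set_metrics("X1", truth, uni), "universe")
  # J <= sensitivity always (A∪B >= B)
  set.seed(7)
  for (i in 1:5) {
    A <- sample(uni, 60)
    B <- sample(uni, 80)
    m <- set_metrics(A, B, uni)
    expect_lte(m$jaccard, m$sensitivity)
  }
})

test_that("gene_recovery_correlation behaves at the extremes", {
  set.seed(8)
  truth <- matrix(rnorm(300), 30, 10,
                  dimnames = list(sprintf("G%d", 1:30), sprintf("C%d", 1:10)))
  expect_equal(as.numeric(gene_recovery_correlation(truth, truth, rownames(truth))), 1)
  shuffled <- truth[, sample(10)]
  colnames(shuffled) <- colnames(truth)
  r <- as.numeric(gene_recovery_correlation(shuffled, truth, rownames(truth)))
  expect_lt(abs(r), 0.35)  # 10 cells: noisy but near zero
  # constant genes are excluded with a count
  truth2 <- truth
  truth2[1, ] <- 5
  got <- gene_recovery_correlation(truth2, truth, rownames(truth))
  expect_equal(attr(got, "n_excluded"), 1)
  expect_error(gene_recovery_correlation(truth, truth, character(0)), "empty")
  expect_error(gene_recovery_correlation(truth, truth, "nope"), "unknown")
})

test_that("snn_cluster recovers two separated simulated groups", {
  sim <- splat_simulate(sim_params(seed = 31, de_fac_loc = 0.3, dropout_mid = -10,
                                   cells_per_group = 100, n_genes = 150))
  norm <- log_normalize(sim$counts)
  cl <- snn_cluster(norm)
  expect_equal(adjusted_rand_index(cl$labels, sim$group_labels), 1)
  expect_identical(dim(cl$embedding), c(200L, 2L))
  # cell-duplicated dataset: copies share their partner's cluster
  dup <- cbind(norm$values, norm$values)
  colnames(dup) <- sprintf("C%d", seq_len(ncol(dup)))
  cl2 <- snn_cluster(dup, embed = FALSE)
  expect_equal(adjusted_rand_index(cl2$labels[1:200], cl2$labels[201:400]), 1)
  expect_error(snn_cluster(matrix(1, 5, 10)), "degenerate")
})

test_that("run_benchmark produces one row per method and rep", {
  grid <- data.frame(de_fac_loc = 0.3, dropout_mid = 2)
  bench <- run_benchmark(grid, cci_params(m = 5, seed = 1, umap_epochs = 50),
                         reps = 1, cells_per_group = 75, n_genes = 150,
                         compute_de = FALSE)
  expect_setequal(bench$method, c("without_dropout", "with_dropout", "cci"))
  expect_equal(nrow(bench), 3)
  wd <- bench[bench$method == "without_dropout", ]
  expect_equal(wd$mean_spearman, 1)
  summ <- summarize_benchmark(bench)
  expect_equal(nrow(summ), 3)
  expect_true(all(c("ari", "mean_spearman") %in% names(summ)))
})
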