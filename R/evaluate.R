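# Louvain communities on a shared nearest-neighbor graph built from PCA
# coordinates. The resolution is the smallest value on `res_grid` yielding at
# least two communities, which calibrates the dropout-free control to its two
# simulated groups while staying deterministic across dataset sizes.
.snn_labels <- function(pcs, n_neighbors = 20, prune = 1 / 15,
                        res_grid = c(0.05, 0.1, 0.2, 0.4, 0.8)) {
  n <- nrow(pcs)
  kk <- min(n_neighbors, n - 1)
  nn <- RANN::nn2(pcs, k = kk + 1)$nn.idx      # includes self
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = kk + 1),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)            # |N(i) intersect N(j)|
  snn <- shared / (2 * (kk + 1) - shared)      # Jaccard overlap
  snn@x[snn@x < prune] <- 0
  snn <- Matrix::drop0(snn)
  g <- igraph::graph_from_adjacency_matrix(snn, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  labels <- rep(1L, n)
  res_used <- res_grid[length(res_grid)]
  for (res in res_grid) {
    lab <- with_seed(42L, igraph::cluster_louvain(g, resolution = res)$membership)
    if (length(unique(lab)) >= 2) {
      labels <- lab
      res_used <- res
      break
    }
    labels <- lab
  }
  list(labels = as.integer(labels), resolution = res_used)
}

#' Shared nearest-neighbor clustering of cells
#'
#' Seurat-style pipeline: genes are scaled, cells reduced by PCA, a k-nearest
#' neighbor graph is weighted by the Jaccard overlap of neighbor sets (edges
#' below the prune threshold dropped), and Louvain community detection is run
#' at the smallest resolution on a fixed grid that yields at least two
#' communities. Optionally also returns a 2-D UMAP of the PCA space for
#' plotting and compactness.
#'
#' @param x a `cci_norm`, `cci_imputed`, or gene x cell matrix on a log scale.
#' @param n_features cap on the number of variable genes used (default 2000,
#'   i.e. all genes for typical simulated matrices).
#' @param pca_dim PCA depth.
#' @param n_neighbors neighbors for the kNN graph.
#' @param prune minimum Jaccard overlap kept as an edge.
#' @param res_grid candidate Louvain resolutions, ascending.
#' @param embed also compute the 2-D UMAP embedding.
#' @return a `cci_clustering` object: `labels` (integer per cell),
#'   `embedding` (cell x 2 matrix or `NULL`), `resolution`.
#' @export
snn_cluster <- function(x, n_features = 2000, pca_dim = 30, n_neighbors = 20,
                        prune = 1 / 15, res_grid = c(0.05, 0.1, 0.2, 0.4, 0.8),
                        embed = TRUE) {
  v <- if (inherits(x, "cci_norm") || inherits(x, "cci_imputed")) x$values else x
  stopifnot(is.matrix(v))
  if (ncol(v) < 3) stop("snn_cluster: need at least 3 cells")
  if (all(apply(v, 1, stats::sd) == 0))
    stop("snn_cluster: degenerate constant matrix")
  norm <- as_normalized(v)
  nf <- min(n_features, nrow(v))
  feats <- select_variable_genes(norm, nf)
  sub <- scale_genes(as_normalized(v[feats, , drop = FALSE]))
  pcs <- .pca_cells(sub$values, pca_dim)
  res <- .snn_labels(pcs, n_neighbors = n_neighbors, prune = prune,
                     res_grid = res_grid)
  embedding <- NULL
  if (embed) {
    nb <- max(2, min(15, ncol(v) - 1))
    embedding <- with_seed(99L,
      uwot::umap(pcs, n_neighbors = nb, n_threads = 1, n_sgd_threads = 0))
    rownames(embedding) <- colnames(v)
  }
  structure(list(labels = res$labels, embedding = embedding,
                 resolution = res$resolution),
            class = "cci_clustering")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model:
#' 1 for identical partitions (up to relabeling), approximately 0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return a scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("adjusted_rand_index: label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Compactness of a clustering in an embedding
#'
#' The between-group share of total variance, `B / (B + W)`, where
#' `B = sum_k n_k ||xbar_k - xbar||^2` and
#' `W = sum_k sum_{i in k} ||x_i - xbar_k||^2`. By the ANOVA decomposition
#' `B + W` equals the total sum of squares about the grand mean. Values near
#' 1 indicate tight, well-separated clusters. Reported compactness depends on
#' the embedding space; this package evaluates it on the 2-D UMAP of the
#' matrix under study.
#'
#' @param points cell x d coordinate matrix.
#' @param labels per-cell cluster labels.
#' @return a scalar in `[0, 1]`; a single cluster returns 0 with a warning.
#' @export
compactness <- function(points, labels) {
  points <- as.matrix(points)
  if (nrow(points) != length(labels))
    stop("compactness: points and labels differ in length")
  if (length(unique(labels)) < 2) {
    warning("compactness: single cluster; between-group variance undefined, returning 0")
    return(0)
  }
  grand <- colMeans(points)
  B <- 0
  W <- 0
  for (k in unique(labels)) {
    idx <- labels == k
    ctr <- colMeans(points[idx, , drop = FALSE])
    B <- B + sum(idx) * sum((ctr - grand)^2)
    W <- W + sum(sweep(points[idx, , drop = FALSE], 2, ctr)^2)
  }
  if (B + W == 0) return(1)  # all points identical at distinct... degenerate
  B / (B + W)
}

# vectorized two-sided Wilcoxon rank-sum p-values (normal approximation with
# tie correction and continuity correction), one row of `x` per gene.
.rank_sum_p <- function(x, in_a) {
  n1 <- sum(in_a)
  n2 <- sum(!in_a)
  n <- n1 + n2
  apply(x, 1, function(v) {
    r <- rank(v)
    U <- sum(r[in_a]) - n1 * (n1 + 1) / 2
    tie_tab <- table(v)
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sig2 <= 0) return(1)
    z <- U - n1 * n2 / 2
    z <- (abs(z) - 0.5) / sqrt(sig2)   # continuity correction
    if (z < 0) z <- 0
    2 * stats::pnorm(-z)
  })
}

#' Wilcoxon rank-sum differential expression between two clusters
#'
#' Per gene, a two-sided Wilcoxon rank-sum test between the two clusters
#' (the two largest, with a message, when more than two are supplied);
#' p-values are multiplicity adjusted (Bonferroni by default, matching the
#' Seurat marker-test default; Benjamini-Hochberg available). The log
#' fold-change is computed Seurat-style on de-logged means:
#' `log2((mean(expm1(x)) + 1)_A / (mean(expm1(x)) + 1)_B)`. A gene is
#' declared DE when `adj_p < alpha` and `|lfc| >= lfc_min`.
#'
#' @param x a `cci_norm`, `cci_imputed`, or gene x cell log-scale matrix.
#' @param labels per-cell cluster labels (>= 2 clusters, each with >= 3 cells).
#' @param alpha adjusted-p threshold.
#' @param lfc_min minimum absolute log2 fold-change.
#' @param adjust `"bonferroni"` or `"BH"`.
#' @return a `cci_de` object: `table` (data.frame with gene, p, adj_p, lfc,
#'   declared) and `declared` (character vector of declared DE genes).
#' @export
wilcoxon_de <- function(x, labels, alpha = 0.05, lfc_min = 0.2,
                        adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  v <- if (inherits(x, "cci_norm") || inherits(x, "cci_imputed")) x$values else x
  stopifnot(is.matrix(v))
  if (ncol(v) != length(labels)) stop("wilcoxon_de: labels do not match cells")
  tab <- sort(table(labels), decreasing = TRUE)
  if (length(tab) < 2) stop("wilcoxon_de: need at least 2 clusters")
  if (length(tab) > 2)
    message("wilcoxon_de: ", length(tab), " clusters supplied; using the largest two")
  top <- names(tab)[1:2]
  if (any(tab[1:2] < 3)) stop("wilcoxon_de: a contrasted cluster has fewer than 3 cells")
  keep <- labels %in% top
  vv <- v[, keep, drop = FALSE]
  in_a <- labels[keep] == top[1]
  p <- .rank_sum_p(vv, in_a)
  mean_a <- rowMeans(expm1(vv[, in_a, drop = FALSE]))
  mean_b <- rowMeans(expm1(vv[, !in_a, drop = FALSE]))
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  adj_p <- stats::p.adjust(p, method = adjust)
  declared <- adj_p < alpha & abs(lfc) >= lfc_min
  res <- data.frame(gene = rownames(v), p = p, adj_p = adj_p, lfc = lfc,
                    declared = declared, row.names = NULL)
  structure(list(table = res, declared = res$gene[res$declared],
                 clusters = top, alpha = alpha, lfc_min = lfc_min),
            class = "cci_de")
}

#' Jaccard index, sensitivity, and specificity of a declared gene set
#'
#' With declared set A, true set B and universe Omega:
#' `J = |A∩B| / |A∪B|`, `sensitivity = |A∩B| / |B|`,
#' `specificity = |(Omega\\A) ∩ (Omega\\B)| / |Omega\\B|`.
#'
#' @param declared,truth,universe character vectors; `declared` and `truth`
#'   must be subsets of `universe`.
#' @return named list with `jaccard`, `sensitivity`, `specificity`;
#'   `sensitivity` is `NA` for an empty truth set, `jaccard` is `NA` when
#'   both sets are empty.
#' @export
set_metrics <- function(declared, truth, universe) {
  declared <- unique(as.character(declared))
  truth <- unique(as.character(truth))
  universe <- unique(as.character(universe))
  if (!all(declared %in% universe)) stop("set_metrics: declared set outside the universe")
  if (!all(truth %in% universe)) stop("set_metrics: truth set outside the universe")
  inter <- length(intersect(declared, truth))
  uni <- length(union(declared, truth))
  non_truth <- setdiff(universe, truth)
  list(jaccard = if (uni == 0) NA_real_ else inter / uni,
       sensitivity = if (length(truth) == 0) NA_real_ else inter / length(truth),
       specificity = if (length(non_truth) == 0) NA_real_
                     else length(setdiff(non_truth, declared)) / length(non_truth))
}

#' Mean per-gene Spearman correlation between two matrices
#'
#' For each gene in `genes`, the Spearman rank correlation across cells
#' between the two matrices; the mean over genes is returned. Genes constant
#' in either matrix have an undefined correlation and are excluded (count
#' reported via attribute `n_excluded`).
#'
#' @param imputed,truth matrices or `cci_norm`/`cci_imputed` objects with
#'   matching dimensions and gene names.
#' @param genes gene identifiers to average over (e.g. the true DE genes).
#' @return mean Spearman correlation (scalar) with attribute `n_excluded`.
#' @export
gene_recovery_correlation <- function(imputed, truth, genes) {
  a <- if (inherits(imputed, "cci_norm") || inherits(imputed, "cci_imputed")) imputed$values else imputed
  b <- if (inherits(truth, "cci_norm") || inherits(truth, "cci_imputed")) truth$values else truth
  if (!all(dim(a) == dim(b))) stop("gene_recovery_correlation: dimension mismatch")
  if (length(genes) == 0) stop("gene_recovery_correlation: empty gene set")
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(a))
  if (length(missing) > 0)
    stop("gene_recovery_correlation: unknown gene(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  rho <- vapply(genes, function(g) {
    suppressWarnings(stats::cor(a[g, ], b[g, ], method = "spearman"))
  }, numeric(1))
  bad <- is.na(rho)
  if (all(bad)) stop("gene_recovery_correlation: all correlations undefined")
  out <- mean(rho[!bad])
  attr(out, "n_excluded") <- sum(bad)
  out
}

#' Simulation benchmark over a grid of signal and dropout levels
#'
#' For each grid row and repetition: simulate, corrupt with dropout,
#' log-normalize, impute with CCI, and evaluate the clustering (adjusted Rand
#' index against the simulated groups, compactness on the UMAP embedding), DE
#' calling (Jaccard/sensitivity/specificity against the true DE genes), and
#' per-gene Spearman recovery — for the dropout-free control, the corrupted
#' matrix, and the imputed matrix. Externally imputed matrices can join the
#' comparison through `extra_methods`.
#'
#' @param grid data.frame with columns `de_fac_loc` and `dropout_mid` (one
#'   row per setting).
#' @param params a [cci_params()] object.
#' @param reps repetitions per setting.
#' @param cells_per_group,n_genes simulated dataset size.
#' @param seed base seed; each (setting, rep) derives its own substream.
#' @param compute_de also run the Wilcoxon DE evaluation (slower).
#' @param extra_methods named list of functions `f(norm_dropout)` returning a
#'   gene x cell imputed matrix on the log scale.
#' @return data.frame with one row per (setting, rep, method) and columns
#'   `ari`, `compactness`, `jaccard`, `sensitivity`, `specificity`,
#'   `mean_spearman`; summarize with [summarize_benchmark()].
#' @export
run_benchmark <- function(grid, params = cci_params(), reps = 1,
                          cells_per_group = 500, n_genes = 500, seed = 1L,
                          compute_de = TRUE, extra_methods = NULL) {
  stopifnot(is.data.frame(grid), all(c("de_fac_loc", "dropout_mid") %in% names(grid)),
            reps >= 1)
  rows <- list()
  for (s in seq_len(nrow(grid))) {
    for (r in seq_len(reps)) {
      ds_seed <- derive_seed(seed, "benchmark", s * 1000L + r)
      row <- tryCatch(
        .benchmark_one(grid$de_fac_loc[s], grid$dropout_mid[s], ds_seed,
                       params, cells_per_group, n_genes, compute_de,
                       extra_methods),
        error = function(e) {
          warning("benchmark rep failed (setting ", s, ", rep ", r, "): ",
                  conditionMessage(e))
          NULL
        })
      if (!is.null(row)) {
        row$setting <- s
        row$de_fac_loc <- grid$de_fac_loc[s]
        row$dropout_mid <- grid$dropout_mid[s]
        row$rep <- r
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  do.call(rbind, rows)
}

.benchmark_one <- function(de_fac_loc, dropout_mid, seed, params,
                           cells_per_group, n_genes, compute_de,
                           extra_methods) {
  sim <- splat_simulate(sim_params(seed = seed, de_fac_loc = de_fac_loc,
                                   dropout_mid = dropout_mid,
                                   cells_per_group = cells_per_group,
                                   n_genes = n_genes))
  norm_true <- log_normalize(sim$counts)
  norm_drop <- log_normalize(sim$counts_dropout)
  run <- cci_run(norm_drop, params)
  mats <- list(without_dropout = norm_true$values,
               with_dropout = norm_drop$values,
               cci = run$imputed$values)
  for (nm in names(extra_methods))
    mats[[nm]] <- extra_methods[[nm]](norm_drop)
  out <- lapply(names(mats), function(nm) {
    v <- mats[[nm]]
    cl <- snn_cluster(v, embed = TRUE)
    ari <- adjusted_rand_index(cl$labels, sim$group_labels)
    cmp <- if (length(unique(cl$labels)) >= 2)
      compactness(cl$embedding, cl$labels) else 0
    jac <- sens <- spec <- NA_real_
    if (compute_de && length(unique(cl$labels)) >= 2) {
      de <- suppressMessages(wilcoxon_de(v, cl$labels))
      sm <- set_metrics(de$declared, sim$true_de_genes, rownames(v))
      jac <- sm$jaccard; sens <- sm$sensitivity; spec <- sm$specificity
    }
    sp <- if (nm == "without_dropout") 1
      else as.numeric(gene_recovery_correlation(v, norm_true$values, sim$true_de_genes))
    data.frame(method = nm, ari = ari, compactness = cmp, jaccard = jac,
               sensitivity = sens, specificity = spec, mean_spearman = sp)
  })
  do.call(rbind, out)
}

#' Summarize a benchmark table into mean (sd) per method
#'
#' Averages per-setting means (and standard deviations across repetitions)
#' over all settings, one row per method — the layout of a methods-comparison
#' summary table.
#'
#' @param bench output of [run_benchmark()].
#' @return data.frame with per-method averaged means and sds.
#' @export
summarize_benchmark <- function(bench) {
  metrics <- c("ari", "compactness", "jaccard", "sensitivity", "specificity",
               "mean_spearman")
  out <- lapply(split(bench, bench$method), function(d) {
    per_setting <- lapply(split(d, d$setting), function(ds) {
      c(vapply(metrics, function(m) mean(ds[[m]], na.rm = TRUE), numeric(1)),
        vapply(metrics, function(m) if (nrow(ds) > 1) stats::sd(ds[[m]], na.rm = TRUE) else 0,
               numeric(1)))
    })
    avg <- colMeans(do.call(rbind, per_setting), na.rm = TRUE)
    data.frame(method = d$method[1],
               t(stats::setNames(avg, c(metrics, paste0(metrics, "_sd")))))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.cci_clustering <- function(x, ...) {
  cat(sprintf("SNN clustering: %d cells, %d communities (resolution %.2f)\n",
              length(x$labels), length(unique(x$labels)), x$resolution))
  invisible(x)
}

#' @export
print.cci_de <- function(x, ...) {
  cat(sprintf("Wilcoxon DE: %d genes tested, %d declared (adj p < %g, |lfc| >= %g)\n",
              nrow(x$table), length(x$declared), x$alpha, x$lfc_min))
  invisible(x)
}
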