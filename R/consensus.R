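#' Tuning parameters for consensus-clustering imputation
#'
#' Defaults follow the configuration selected by sensitivity analysis for
#' two-group droplet data: sample `p = 0.8` of a pool of the `gene_pool = 100`
#' most variable genes, cluster each subset into `k = 4` groups with K-means
#' on a 2-D UMAP of the subset's PCA, repeat `m = 50` times, and keep
#' consensus entries at or above `c = 0.2` as neighbor weights.
#'
#' @param p proportion of the gene pool sampled per iteration, in (0, 1].
#' @param gene_pool size of the variable-gene pool sampled from, or `"all"`.
#' @param k number of K-means clusters per subset (k >= 2 captures structure;
#'   small k emphasizes global patterns, large k local ones).
#' @param m number of subsets / clustering runs.
#' @param c consensus cutoff in `[0, 1]` defining neighbors.
#' @param epsilon ridge added to the weight sum so neighborless cells impute
#'   to zero instead of 0/0.
#' @param weighting `"weighted"` (consensus-weighted average) or
#'   `"unweighted"` (plain mean over qualifying neighbors).
#' @param cluster_method `"kmeans"` (default, fast) or `"snn"` (shared
#'   nearest-neighbor graph clustering) for the in-loop clustering.
#' @param seed base seed; per-iteration substreams derive from it, so
#'   iterations are order-independent.
#' @param pca_dim PCA depth before UMAP (capped by subset size).
#' @param umap_neighbors,umap_min_dist,umap_epochs UMAP hyperparameters for
#'   the in-loop embedding.
#' @param kmeans_nstart K-means restarts.
#' @return a validated `cci_params` list.
#' @export
cci_params <- function(p = 0.8, gene_pool = 100, k = 4, m = 50, c = 0.2,
                       epsilon = 1e-6, weighting = c("weighted", "unweighted"),
                       cluster_method = c("kmeans", "snn"), seed = 1L,
                       pca_dim = 30, umap_neighbors = 15, umap_min_dist = 0.01,
                       umap_epochs = 200, kmeans_nstart = 10) {
  weighting <- match.arg(weighting)
  cluster_method <- match.arg(cluster_method)
  if (!is.numeric(p) || p <= 0 || p > 1) stop("cci_params: p must be in (0, 1]")
  if (!identical(gene_pool, "all") &&
      (!is.numeric(gene_pool) || gene_pool < 2 || gene_pool != round(gene_pool)))
    stop("cci_params: gene_pool must be an integer >= 2 or \"all\"")
  if (!is.numeric(k) || k < 2 || k != round(k)) stop("cci_params: k must be an integer >= 2")
  if (!is.numeric(m) || m < 1 || m != round(m)) stop("cci_params: m must be an integer >= 1")
  if (!is.numeric(c) || c < 0 || c > 1) stop("cci_params: c must be in [0, 1]")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("cci_params: epsilon must be > 0")
  structure(list(p = p, gene_pool = gene_pool, k = as.integer(k),
                 m = as.integer(m), c = c, epsilon = epsilon,
                 weighting = weighting, cluster_method = cluster_method,
                 seed = as.integer(seed), pca_dim = as.integer(pca_dim),
                 umap_neighbors = as.integer(umap_neighbors),
                 umap_min_dist = umap_min_dist,
                 umap_epochs = as.integer(umap_epochs),
                 kmeans_nstart = as.integer(kmeans_nstart)),
            class = "cci_params")
}

#' Sample a gene subset without replacement
#'
#' Draws `floor(p * length(gene_ids))` distinct genes uniformly. Uses the
#' caller's RNG state; [build_consensus()] wraps it in per-iteration
#' substreams.
#'
#' @param gene_ids candidate gene identifiers.
#' @param p sampling proportion in (0, 1].
#' @return character vector of sampled gene ids.
#' @export
subsample_genes <- function(gene_ids, p) {
  if (length(gene_ids) == 0) stop("subsample_genes: empty gene list")
  if (!is.numeric(p) || p <= 0 || p > 1) stop("subsample_genes: p must be in (0, 1]")
  size <- floor(p * length(gene_ids))
  if (size < 2)
    stop("subsample_genes: subset size ", size, " < 2; cannot embed (raise p or the pool size)")
  if (size == length(gene_ids)) return(gene_ids)
  gene_ids[sort.int(sample.int(length(gene_ids), size))]
}

#' Embed a gene subset into two dimensions (PCA then UMAP)
#'
#' PCA reduces the scaled subset to at most `pca_dim` components (capped at
#' genes - 1 and cells - 1), then UMAP maps the components to 2-D. With a
#' fixed RNG state the embedding is deterministic (single-threaded SGD).
#'
#' @param scaled gene x cell matrix of scaled values (see [scale_genes()]).
#' @param pca_dim PCA depth.
#' @param n_neighbors,min_dist,n_epochs UMAP hyperparameters.
#' @return cell x 2 coordinate matrix.
#' @export
embed_subset <- function(scaled, pca_dim = 30, n_neighbors = 15,
                         min_dist = 0.01, n_epochs = 200) {
  if (inherits(scaled, "cci_norm")) scaled <- scaled$values
  stopifnot(is.matrix(scaled))
  if (nrow(scaled) < 2) stop("embed_subset: need at least 2 genes")
  if (all(apply(scaled, 1, stats::sd) == 0))
    stop("embed_subset: degenerate all-constant subset")
  d <- min(pca_dim, nrow(scaled) - 1, ncol(scaled) - 1)
  pcs <- .pca_cells(scaled, d)
  nb <- max(2, min(n_neighbors, ncol(scaled) - 1))
  uwot::umap(pcs, n_components = 2, n_neighbors = nb, min_dist = min_dist,
             n_epochs = n_epochs, n_threads = 1, n_sgd_threads = 0)
}

# PCA of cells (columns) from a gene x cell matrix; truncated solve for
# large problems, exact otherwise. Rows of the result are cells.
.pca_cells <- function(mat, d) {
  x <- t(mat)
  d <- max(1, min(d, ncol(x) - 1, nrow(x) - 1))
  if (ncol(x) > 100 && d < ncol(x) / 3) {
    x <- sweep(x, 2, colMeans(x))
    sv <- irlba::irlba(x, nv = d)
    pcs <- sv$u %*% diag(sv$d, d, d)
  } else {
    pcs <- stats::prcomp(x, rank. = d, center = TRUE, scale. = FALSE)$x
  }
  rownames(pcs) <- rownames(x)
  pcs
}

#' Cluster an embedding with K-means
#'
#' K-means with multiple restarts on the 2-D embedding. Cluster indices carry
#' no meaning across subsets; only co-membership is used downstream.
#'
#' @param embedding cell x d coordinate matrix.
#' @param k number of clusters (`k <=` number of cells).
#' @param nstart restarts.
#' @return integer labels in `1..k`.
#' @export
cluster_subset <- function(embedding, k, nstart = 10) {
  stopifnot(is.matrix(embedding) || is.data.frame(embedding))
  embedding <- as.matrix(embedding)
  if (k > nrow(embedding)) stop("cluster_subset: k exceeds the number of cells")
  if (k == 1) return(rep(1L, nrow(embedding)))
  stats::kmeans(embedding, centers = k, nstart = nstart, iter.max = 100)$cluster
}

#' Binary co-membership matrix of a clustering
#'
#' Entry (i, j) is 1 when cells i and j share a label, else 0; symmetric with
#' unit diagonal. Invariant under relabeling of clusters.
#'
#' @param labels per-cell cluster labels.
#' @return cell x cell 0/1 matrix.
#' @export
co_membership <- function(labels) {
  if (anyNA(labels)) stop("co_membership: labels must be complete")
  out <- outer(labels, labels, "==") * 1
  if (!is.null(names(labels))) dimnames(out) <- list(names(labels), names(labels))
  out
}

#' Build the consensus matrix by repeated gene subsampling
#'
#' Runs the subsample/embed/cluster loop `m` times on a pool of variable
#' genes and averages the co-membership matrices. Entry (i, j) of the result
#' is the fraction of runs in which cells i and j co-clustered — the
#' similarity score used for imputation. Each iteration draws from a
#' substream derived from `(seed, iteration)`, so results do not depend on
#' execution order. Memory is quadratic in the number of cells.
#'
#' @param norm a `cci_norm` object (unscaled log-normalized values).
#' @param params a [cci_params()] object.
#' @param store_labels keep the per-iteration label vectors (for diagnostics
#'   and oracle checks).
#' @return a `cci_consensus` object: `entries` (cell x cell matrix in
#'   `[0, 1]`), `m_used`, `gene_pool` (the pool ids), `params`, and
#'   optionally `labels` (list of per-iteration label vectors).
#' @export
build_consensus <- function(norm, params = cci_params(), store_labels = FALSE) {
  stopifnot(inherits(norm, "cci_norm"), inherits(params, "cci_params"))
  if (isTRUE(norm$is_scaled))
    stop("build_consensus: pass the unscaled log-normalized matrix")
  ncells <- ncol(norm$values)
  if (ncells < params$k) stop("build_consensus: fewer cells than clusters k")
  pool_n <- if (identical(params$gene_pool, "all")) nrow(norm$values)
            else min(params$gene_pool, nrow(norm$values))
  pool <- select_variable_genes(norm, pool_n)

  acc <- matrix(0, ncells, ncells,
                dimnames = list(colnames(norm$values), colnames(norm$values)))
  labels_kept <- if (store_labels) vector("list", params$m) else NULL
  for (it in seq_len(params$m)) {
    iter_seed <- derive_seed(params$seed, "consensus", it)
    labels <- with_seed(iter_seed, {
      genes <- subsample_genes(pool, params$p)
      sub <- scale_genes(as_normalized(norm$values[genes, , drop = FALSE]))
      emb <- embed_subset(sub$values, pca_dim = params$pca_dim,
                          n_neighbors = params$umap_neighbors,
                          min_dist = params$umap_min_dist,
                          n_epochs = params$umap_epochs)
      if (params$cluster_method == "kmeans") {
        cluster_subset(emb, params$k, nstart = params$kmeans_nstart)
      } else {
        pcs <- .pca_cells(sub$values, params$pca_dim)
        .snn_labels(pcs)$labels
      }
    })
    if (store_labels) labels_kept[[it]] <- labels
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      acc[idx, idx] <- acc[idx, idx] + 1
    }
  }
  structure(list(entries = acc / params$m, m_used = params$m,
                 gene_pool = pool, params = params, labels = labels_kept),
            class = "cci_consensus")
}

#' @export
print.cci_consensus <- function(x, ...) {
  off <- x$entries[upper.tri(x$entries)]
  cat(sprintf("Consensus matrix: %d cells, m = %d runs\n", nrow(x$entries), x$m_used))
  cat(sprintf("  off-diagonal entries: mean %.3f, %.1f%% >= 0.5\n",
              mean(off), 100 * mean(off >= 0.5)))
  invisible(x)
}
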