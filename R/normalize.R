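#' Library-size log normalization
#'
#' Seurat-style log normalization: each cell's counts are divided by the
#' cell's total, multiplied by `scale_factor`, and `log1p`-transformed.
#' Zero counts map to exactly zero, so the zero pattern (and hence the set of
#' entries eligible for imputation) is preserved.
#'
#' @param counts nonnegative gene x cell matrix (dense or `Matrix` sparse);
#'   gene and cell identifiers are taken from dimnames or generated.
#' @param scale_factor target per-cell total on the count scale (default 10000).
#' @return a `cci_norm` object: list with `values` (dense gene x cell matrix,
#'   natural-log scale), `scale_factor`, `is_scaled = FALSE`.
#' @examples
#' m <- matrix(rpois(50, 5), 10, 5)
#' norm <- log_normalize(m)
#' colSums(expm1(norm$values))  # all equal scale_factor
#' @export
log_normalize <- function(counts, scale_factor = 10000) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  stopifnot(is.matrix(counts), is.numeric(counts))
  if (any(counts < 0)) stop("log_normalize: counts must be nonnegative")
  if (scale_factor <= 0) stop("log_normalize: scale_factor must be positive")
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("Gene%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("Cell%d", seq_len(ncol(counts)))
  totals <- colSums(counts)
  if (any(totals == 0)) {
    bad <- colnames(counts)[totals == 0]
    stop("log_normalize: cell(s) with zero total counts: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "",
         " (filter empty cells upstream)")
  }
  values <- log1p(sweep(counts, 2, totals, "/") * scale_factor)
  structure(list(values = values, scale_factor = scale_factor, is_scaled = FALSE),
            class = "cci_norm")
}

#' Wrap an externally normalized matrix
#'
#' For matrices already on a log scale (e.g. produced by another tool), so
#' they can enter the pipeline without re-normalization.
#'
#' @param values gene x cell numeric matrix on a log scale.
#' @param scale_factor bookkeeping only.
#' @return a `cci_norm` object.
#' @export
as_normalized <- function(values, scale_factor = NA_real_) {
  if (inherits(values, "Matrix")) values <- as.matrix(values)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) rownames(values) <- sprintf("Gene%d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("Cell%d", seq_len(ncol(values)))
  structure(list(values = values, scale_factor = scale_factor, is_scaled = FALSE),
            class = "cci_norm")
}

#' Center and standardize each gene
#'
#' Subtracts the per-gene mean and divides by the per-gene standard
#' deviation. Genes with zero variance become all-zero rows. Scaling is used
#' only for embedding (PCA/UMAP); imputation always consumes the unscaled
#' log-normalized values, which live on the expression scale.
#'
#' @param norm a `cci_norm` object.
#' @return the object with `values` standardized and `is_scaled = TRUE`.
#' @export
scale_genes <- function(norm) {
  stopifnot(inherits(norm, "cci_norm"))
  if (isTRUE(norm$is_scaled)) stop("scale_genes: matrix is already scaled")
  v <- norm$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  s <- (v - mu) / sdv
  s[sdv == 0, ] <- 0
  norm$values <- s
  norm$is_scaled <- TRUE
  norm
}

# standardized dispersion used to rank genes: residual of log10 variance
# around a loess trend on log10 mean (computed on log-normalized values).
# Falls back to raw variance when too few informative genes for a fit.
.gene_dispersion <- function(values) {
  v <- apply(values, 1, stats::var)
  mu <- rowMeans(values)
  disp <- rep(-Inf, length(v))
  ok <- v > 0
  if (sum(ok) >= 5 && stats::sd(mu[ok]) > 0) {
    fit <- stats::loess(log10(v[ok]) ~ log10(mu[ok] + 1e-8), span = 0.5,
                        degree = 2)
    disp[ok] <- log10(v[ok]) - stats::predict(fit)
  } else {
    disp[ok] <- v[ok]
  }
  list(dispersion = disp, mean = mu)
}

#' Rank genes by variance-stabilized dispersion and return the top n
#'
#' Genes are ranked by the standardized dispersion of their log-normalized
#' values (variance residual around a mean-variance trend), so highly
#' expressed genes do not dominate purely through scale. Ties break toward
#' the higher-mean gene, then lexicographic gene id; constant genes rank
#' last. The ranking is invariant to gene (row) order.
#'
#' @param norm a `cci_norm` object (unscaled).
#' @param n how many genes to return (`n <=` number of genes).
#' @return character vector of `n` gene identifiers, most variable first.
#' @export
select_variable_genes <- function(norm, n) {
  stopifnot(inherits(norm, "cci_norm"))
  if (!is.numeric(n) || length(n) != 1L || n <= 0 || n != round(n))
    stop("select_variable_genes: n must be a positive integer")
  v <- norm$values
  if (n > nrow(v)) stop("select_variable_genes: n exceeds the number of genes")
  ids <- rownames(v)
  d <- .gene_dispersion(v)
  ord <- order(-d$dispersion, -d$mean, ids)
  ids[ord][seq_len(n)]
}

#' @export
print.cci_norm <- function(x, ...) {
  cat(sprintf("Normalized expression matrix: %d genes x %d cells (%s)\n",
              nrow(x$values), ncol(x$values),
              if (isTRUE(x$is_scaled)) "scaled" else "log scale"))
  invisible(x)
}
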