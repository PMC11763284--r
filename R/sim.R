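#' Parameters for the Splat-style count simulator
#'
#' The generator follows the Splat model for droplet scRNA-seq counts: gene
#' base means are Gamma distributed, a few expression-outlier genes are
#' inflated to a log-normal multiple of the median base mean, group
#' differential-expression (DE) factors are log-normal (optionally inverted to
#' model down-regulation), per-cell library sizes are log-normal, per-entry
#' means get a biological-coefficient-of-variation (BCV) gamma layer, and
#' counts are Poisson. Dropout is a separate, mean-dependent logistic zeroing
#' step (see [apply_dropout()]).
#'
#' Defaults reproduce a two-group experiment of 2000 cells per group and 500
#' genes with `de_prob = 0.1`, log-normal DE factors
#' (`de_fac_loc`, `de_fac_scale`) and down-regulation probability 0.5; the
#' non-DE parameters (`mean_shape = 0.6`, `mean_rate = 0.3`, `lib_loc = 11`,
#' `lib_scale = 0.2`, outlier and BCV settings) are the Splat documented
#' defaults. The outlier and BCV layers matter for realism: without the
#' outlier genes the simulated matrices are too dense for a given dropout
#' midpoint, because no highly expressed genes absorb library size.
#'
#' @param seed integer seed; every stage draws from a named substream derived
#'   from it.
#' @param ngroups number of cell groups.
#' @param cells_per_group cells simulated per group.
#' @param n_genes number of genes.
#' @param de_prob probability that a gene is DE in a given group.
#' @param de_fac_loc,de_fac_scale location and scale of the log-normal DE
#'   factor; larger `de_fac_loc` means stronger group separation.
#' @param de_down_prob probability that a DE factor is inverted (reciprocal),
#'   i.e. the gene is down-regulated in that group.
#' @param dropout_mid,dropout_shape midpoint (on the natural-log mean scale)
#'   and slope of the logistic dropout curve used by [apply_dropout()].
#' @param mean_shape,mean_rate Gamma shape and rate for gene base means.
#' @param lib_loc,lib_scale log-normal location and scale for library sizes.
#' @param out_prob probability that a gene is an expression outlier.
#' @param out_fac_loc,out_fac_scale log-normal location/scale of the outlier
#'   inflation factor (applied to the median base mean).
#' @param bcv_common,bcv_df common dispersion and degrees of freedom of the
#'   BCV layer; `bcv_common = 0` disables it (pure Poisson).
#' @return a `sim_params` list, validated.
#' @examples
#' p <- sim_params(seed = 1, cells_per_group = 50, n_genes = 100)
#' sim <- simulate_counts(p)
#' dim(sim$counts)
#' @export
sim_params <- function(seed = 1L,
                       ngroups = 2L,
                       cells_per_group = 2000L,
                       n_genes = 500L,
                       de_prob = 0.1,
                       de_fac_loc = 0.1,
                       de_fac_scale = 0.4,
                       de_down_prob = 0.5,
                       dropout_mid = 2,
                       dropout_shape = -1,
                       mean_shape = 0.6,
                       mean_rate = 0.3,
                       lib_loc = 11,
                       lib_scale = 0.2,
                       out_prob = 0.05,
                       out_fac_loc = 4,
                       out_fac_scale = 0.5,
                       bcv_common = 0.1,
                       bcv_df = 60) {
  p <- list(seed = seed, ngroups = ngroups, cells_per_group = cells_per_group,
            n_genes = n_genes, de_prob = de_prob, de_fac_loc = de_fac_loc,
            de_fac_scale = de_fac_scale, de_down_prob = de_down_prob,
            dropout_mid = dropout_mid, dropout_shape = dropout_shape,
            mean_shape = mean_shape, mean_rate = mean_rate,
            lib_loc = lib_loc, lib_scale = lib_scale,
            out_prob = out_prob, out_fac_loc = out_fac_loc,
            out_fac_scale = out_fac_scale,
            bcv_common = bcv_common, bcv_df = bcv_df)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("sim_params: field '", nm, "' must be a finite numeric scalar")
  }
  for (nm in c("de_prob", "de_down_prob", "out_prob")) {
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("sim_params: field '", nm, "' must be a probability in [0, 1]")
  }
  for (nm in c("ngroups", "cells_per_group", "n_genes")) {
    if (p[[nm]] < 1 || p[[nm]] != round(p[[nm]]))
      stop("sim_params: field '", nm, "' must be a positive integer")
    p[[nm]] <- as.integer(p[[nm]])
  }
  for (nm in c("mean_shape", "mean_rate")) {
    if (p[[nm]] <= 0) stop("sim_params: field '", nm, "' must be > 0")
  }
  if (p$bcv_common < 0) stop("sim_params: field 'bcv_common' must be >= 0")
  structure(p, class = "sim_params")
}

#' Simulate group-structured scRNA-seq counts (no dropout)
#'
#' Draws the full Splat-style hierarchy and returns the dropout-free dataset;
#' [apply_dropout()] adds the dropout-corrupted matrix. Given the same
#' parameters (including seed), the result is bit-reproducible.
#'
#' @param params a [sim_params()] object.
#' @return a `sim_dataset` list with elements
#'   \describe{
#'     \item{counts}{gene x cell integer matrix, no dropout.}
#'     \item{counts_dropout}{`NULL` until [apply_dropout()] is run.}
#'     \item{group_labels}{integer vector in `1..ngroups`, one per cell.}
#'     \item{de_factors}{gene x group matrix of DE factors (1 = not DE).}
#'     \item{true_de_genes}{character vector of genes with any group factor != 1.}
#'     \item{cell_means}{gene x cell matrix of realized Poisson means (after
#'       the BCV layer); this is the mean the dropout logistic sees.}
#'     \item{base_means}{gene x cell matrix of expected means before the BCV
#'       layer.}
#'     \item{dropout_mask}{`NULL` until [apply_dropout()] is run.}
#'     \item{params}{the parameter echo.}
#'   }
#' @export
simulate_counts <- function(params) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, as.list(params))
  ng <- params$n_genes
  ncl <- params$ngroups * params$cells_per_group
  gene_ids <- sprintf("Gene%d", seq_len(ng))
  cell_ids <- sprintf("Cell%d", seq_len(ncl))

  base_gene <- with_seed(derive_seed(params$seed, "means"), {
    bm <- stats::rgamma(ng, shape = params$mean_shape, rate = params$mean_rate)
    is_out <- stats::runif(ng) < params$out_prob
    out_fac <- stats::rlnorm(ng, params$out_fac_loc, params$out_fac_scale)
    bm[is_out] <- stats::median(bm) * out_fac[is_out]
    bm
  })

  de_factors <- with_seed(derive_seed(params$seed, "factors"), {
    f <- matrix(1, ng, params$ngroups,
                dimnames = list(gene_ids, paste0("Group", seq_len(params$ngroups))))
    for (g in seq_len(params$ngroups)) {
      is_de <- stats::runif(ng) < params$de_prob
      fac <- exp(stats::rnorm(ng, params$de_fac_loc, params$de_fac_scale))
      down <- stats::runif(ng) < params$de_down_prob
      fac[down] <- 1 / fac[down]
      f[is_de, g] <- fac[is_de]
    }
    f
  })

  lib_sizes <- with_seed(derive_seed(params$seed, "libsizes"),
                         stats::rlnorm(ncl, params$lib_loc, params$lib_scale))

  group_labels <- rep(seq_len(params$ngroups), each = params$cells_per_group)

  group_means <- base_gene * de_factors              # gene x group
  group_props <- sweep(group_means, 2, colSums(group_means), "/")
  base_means <- group_props[, group_labels, drop = FALSE] *
    rep(lib_sizes, each = ng)
  dimnames(base_means) <- list(gene_ids, cell_ids)

  cell_means <- if (params$bcv_common > 0) {
    with_seed(derive_seed(params$seed, "bcv"), {
      bcv <- (params$bcv_common + 1 / sqrt(base_means)) *
        sqrt(params$bcv_df / stats::rchisq(ng, params$bcv_df))
      matrix(stats::rgamma(length(base_means), shape = 1 / bcv^2,
                           scale = base_means * bcv^2),
             ng, ncl, dimnames = dimnames(base_means))
    })
  } else base_means

  counts <- with_seed(derive_seed(params$seed, "counts"),
                      matrix(stats::rpois(length(cell_means), cell_means),
                             ng, ncl, dimnames = dimnames(cell_means)))

  true_de <- gene_ids[apply(de_factors, 1, function(x) any(x != 1))]

  structure(list(counts = counts, counts_dropout = NULL,
                 group_labels = group_labels, de_factors = de_factors,
                 true_de_genes = true_de, cell_means = cell_means,
                 base_means = base_means, dropout_mask = NULL,
                 params = params),
            class = "sim_dataset")
}

#' Logistic dropout probability
#'
#' Probability that a count with true mean `cell_mean` is zeroed by the
#' dropout step: `1 / (1 + exp(-shape * (log(cell_mean) - mid)))`. With the
#' conventional `shape = -1` this is decreasing in the mean — lowly expressed
#' genes drop out more often.
#'
#' @param cell_mean positive mean expression (vectorized).
#' @param mid logistic midpoint on the natural-log mean scale; a mean of
#'   `exp(mid)` drops out with probability 0.5.
#' @param shape logistic slope.
#' @return dropout probabilities in `[0, 1]`.
#' @examples
#' dropout_probability(exp(4), mid = 2, shape = -1)  # 1 / (1 + exp(2))
#' @export
dropout_probability <- function(cell_mean, mid, shape) {
  if (any(!is.finite(cell_mean)) || any(cell_mean <= 0))
    stop("dropout_probability: cell_mean must be positive and finite")
  stopifnot(is.finite(mid), is.finite(shape))
  1 / (1 + exp(-shape * (log(cell_mean) - mid)))
}

#' Zero counts by mean-dependent logistic dropout
#'
#' Each entry of `counts` is independently set to zero with probability
#' [dropout_probability()] of its realized cell mean. The dropout draw uses
#' its own RNG substream, so different dropout patterns can be layered on the
#' same counts by varying `seed` without re-simulating.
#'
#' @param dataset a `sim_dataset` from [simulate_counts()].
#' @param mid,shape logistic parameters; default from the dataset's params.
#' @param seed dropout substream seed; default the dataset seed.
#' @return the dataset with `counts_dropout` and `dropout_mask` filled, plus a
#'   `zero_fraction` attribute-like list element with both accountings of the
#'   dropout rate: `overall` (fraction of zeros in the post-dropout matrix)
#'   and `masked` (fraction of entries zeroed by the dropout step itself).
#' @export
apply_dropout <- function(dataset, mid = NULL, shape = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "sim_dataset"))
  p <- dataset$params
  if (is.null(mid)) mid <- p$dropout_mid
  if (is.null(shape)) shape <- p$dropout_shape
  if (is.null(seed)) seed <- p$seed
  stopifnot(is.finite(mid), is.finite(shape))
  # limit-tolerant logistic: a realized mean of exactly zero (possible under
  # the BCV layer for very lowly expressed genes) gets the limiting dropout
  # probability (1 for negative shape) instead of an error; the corresponding
  # counts are already zero, so only the mask is affected.
  pr <- stats::plogis(shape * (log(dataset$cell_means) - mid))
  mask <- with_seed(derive_seed(seed, "dropout"),
                    matrix(stats::runif(length(pr)) < pr,
                           nrow(pr), ncol(pr), dimnames = dimnames(pr)))
  cd <- dataset$counts
  cd[mask] <- 0L
  dataset$counts_dropout <- cd
  dataset$dropout_mask <- mask
  dataset$zero_fraction <- list(overall = mean(cd == 0), masked = mean(mask))
  dataset
}

#' Simulate counts and apply dropout in one call
#'
#' @param params a [sim_params()] object (its `dropout_mid`/`dropout_shape`
#'   are used for the dropout step).
#' @return a `sim_dataset` with both `counts` and `counts_dropout` filled.
#' @export
splat_simulate <- function(params) {
  apply_dropout(simulate_counts(params))
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated scRNA-seq dataset: %d genes x %d cells, %d groups\n",
              nrow(x$counts), ncol(x$counts), x$params$ngroups))
  cat(sprintf("  true DE genes: %d\n", length(x$true_de_genes)))
  if (!is.null(x$counts_dropout))
    cat(sprintf("  zero fraction after dropout: %.1f%% (%.1f%% zeroed by dropout)\n",
                100 * x$zero_fraction$overall, 100 * x$zero_fraction$masked))
  invisible(x)
}
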