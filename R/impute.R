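#' Neighbor weights from a consensus matrix
#'
#' Applies the neighbor cutoff: weights below `c` are zeroed, weights at or
#' above `c` keep their consensus value. The self-weight is forced to zero —
#' the consensus diagonal is identically 1 and a cell's own value at a zero
#' entry is 0, so including it would only deflate estimates.
#'
#' @param consensus a `cci_consensus` object or a cell x cell matrix in `[0, 1]`.
#' @param c cutoff in `[0, 1]`.
#' @return a `cci_weights` object: `weights` (cell x cell matrix, zero
#'   diagonal) and `c`.
#' @export
neighbor_weights <- function(consensus, c = 0.2) {
  w <- if (inherits(consensus, "cci_consensus")) consensus$entries else consensus
  stopifnot(is.matrix(w))
  if (!is.numeric(c) || c < 0 || c > 1) stop("neighbor_weights: c must be in [0, 1]")
  w[w < c] <- 0
  diag(w) <- 0
  structure(list(weights = w, c = c), class = "cci_weights")
}

# shared core of the two imputation flavors; `w` already has a zero diagonal.
.impute_core <- function(values, w, epsilon) {
  if (ncol(values) != nrow(w))
    stop("impute: matrix has ", ncol(values), " cells but weights have ", nrow(w))
  zero <- values == 0
  # numerator[g, i] = sum_k w_ik x_gk ; denominator_i = sum_k w_ik
  num <- values %*% w                     # w symmetric in practice; use columns of w for cell i
  den <- colSums(w) + epsilon
  est <- sweep(num, 2, den, "/")
  out <- values
  out[zero] <- est[zero]
  structure(list(values = out, imputed_mask = zero, epsilon = epsilon),
            class = "cci_imputed")
}

#' Impute zeros by consensus-weighted neighbor averaging
#'
#' For each zero entry of cell i and gene j, the imputed value is
#' `sum_k w_ik * x_kj / (sum_k w_ik + epsilon)` over neighbor cells k != i.
#' Nonzero entries are copied through unchanged. A cell with no neighbors
#' above the cutoff keeps its zeros (the ridge makes the estimate 0, not
#' NaN), which also preserves biological zeros shared across similar cells.
#'
#' @param norm a `cci_norm` object (unscaled) or gene x cell matrix.
#' @param weights a [neighbor_weights()] object.
#' @param epsilon denominator ridge.
#' @return a `cci_imputed` object: `values` (gene x cell, same scale as
#'   input) and `imputed_mask` (TRUE where the input was zero).
#' @export
impute_weighted <- function(norm, weights, epsilon = 1e-6) {
  v <- if (inherits(norm, "cci_norm")) norm$values else norm
  stopifnot(inherits(weights, "cci_weights"), is.numeric(epsilon), epsilon > 0)
  .impute_core(v, weights$weights, epsilon)
}

#' Impute zeros by a plain mean over qualifying neighbors
#'
#' Same neighbor definition as [impute_weighted()] but every qualifying
#' neighbor counts equally: `sum_k 1(w_ik != 0) x_kj / (sum_k 1(w_ik != 0) +
#' epsilon)`.
#'
#' @inheritParams impute_weighted
#' @return a `cci_imputed` object.
#' @export
impute_unweighted <- function(norm, weights, epsilon = 1e-6) {
  v <- if (inherits(norm, "cci_norm")) norm$values else norm
  stopifnot(inherits(weights, "cci_weights"), is.numeric(epsilon), epsilon > 0)
  .impute_core(v, (weights$weights != 0) * 1, epsilon)
}

#' Run the full consensus-clustering imputation pipeline
#'
#' Composes normalization (optional), consensus construction, neighbor
#' definition, and imputation. The input is either a raw count matrix
#' (normalized internally with [log_normalize()]) or an already normalized
#' matrix (`normalized = TRUE`); imputation operates and stays on the
#' log-normalized scale.
#'
#' @param x gene x cell matrix (counts or normalized values) or `cci_norm`.
#' @param params a [cci_params()] object.
#' @param normalized set TRUE when `x` is already log-normalized.
#' @return a `cci_run` object: `imputed` (`cci_imputed`), `consensus`
#'   (`cci_consensus`), `norm` (the normalized input), `params`, and `meta`
#'   (per-stage timings in seconds and the count of imputed entries).
#' @examples
#' \donttest{
#' sim <- splat_simulate(sim_params(seed = 1, cells_per_group = 100,
#'                                  n_genes = 200, dropout_mid = 4))
#' fit <- cci_run(sim$counts_dropout, cci_params(m = 5, seed = 1))
#' fit$meta$n_imputed
#' }
#' @export
cci_run <- function(x, params = cci_params(), normalized = FALSE) {
  stopifnot(inherits(params, "cci_params"))
  t_all <- proc.time()[["elapsed"]]
  if (inherits(x, "cci_norm")) {
    norm <- x
  } else if (normalized) {
    norm <- as_normalized(x)
  } else {
    norm <- log_normalize(x)
  }
  t0 <- proc.time()[["elapsed"]]
  consensus <- build_consensus(norm, params)
  t_cons <- proc.time()[["elapsed"]] - t0
  w <- neighbor_weights(consensus, params$c)
  t0 <- proc.time()[["elapsed"]]
  imputed <- if (params$weighting == "weighted")
    impute_weighted(norm, w, params$epsilon)
  else impute_unweighted(norm, w, params$epsilon)
  t_imp <- proc.time()[["elapsed"]] - t0
  structure(list(imputed = imputed, consensus = consensus, norm = norm,
                 params = params,
                 meta = list(n_imputed = sum(imputed$imputed_mask),
                             n_cells = ncol(norm$values),
                             n_genes = nrow(norm$values),
                             seconds = list(consensus = t_cons, impute = t_imp,
                                            total = proc.time()[["elapsed"]] - t_all))),
            class = "cci_run")
}

#' @export
print.cci_run <- function(x, ...) {
  cat(sprintf("CCI run: %d genes x %d cells, m = %d, %s imputation\n",
              x$meta$n_genes, x$meta$n_cells, x$params$m, x$params$weighting))
  cat(sprintf("  imputed %d zero entries (%.1f%% of matrix) in %.1fs\n",
              x$meta$n_imputed,
              100 * x$meta$n_imputed / (x$meta$n_genes * x$meta$n_cells),
              x$meta$seconds$total))
  invisible(x)
}

#' @export
print.cci_imputed <- function(x, ...) {
  cat(sprintf("Imputed matrix: %d genes x %d cells, %d entries imputed\n",
              nrow(x$values), ncol(x$values), sum(x$imputed_mask)))
  invisible(x)
}
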