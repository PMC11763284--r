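#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from a single integer seed per run.
#' Named substreams (gene means, DE factors, library sizes, counts, dropout,
#' per-iteration clustering, ...) get their own derived seeds so that one
#' stage can be re-drawn without re-running the others: for example a new
#' dropout pattern can be applied to fixed counts, or consensus iterations can
#' be executed in any order.
#'
#' @param seed base integer seed.
#' @param stream substream name (character scalar).
#' @param index optional iteration index within the substream.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  # modular arithmetic in double precision; all operands < 2^31 so exact
  m <- 2147483647
  s <- (abs(seed) %% m)
  s <- (s * 48271 + h * 31 + index * 7919) %% m
  as.integer(s)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so callers' RNG state is untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
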