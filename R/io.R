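#' Read an expression matrix from MTX or delimited text
#'
#' Matrices are stored gene x cell internally (rows are genes). For MTX the
#' reader looks for `genes.tsv` and `barcodes.tsv` next to the file
#' (10x-style triplet); for CSV/TSV the first column holds gene identifiers
#' and the header holds cell identifiers.
#'
#' @param path file path (`.mtx`, `.csv`, or `.tsv`).
#' @param format `"auto"` (by extension) or explicit.
#' @param orientation `"gene_by_cell"` (default) or `"cell_by_gene"` (the
#'   matrix is transposed on read).
#' @return a dense gene x cell numeric matrix with dimnames (MTX input stays
#'   sparse as a `dgCMatrix`).
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "csv", "tsv"),
                        orientation = c("gene_by_cell", "cell_by_gene")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("read_matrix: no such file: ", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stop("read_matrix: cannot infer format from extension of ", path))
  if (format == "mtx") {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    dir <- dirname(path)
    genes_f <- file.path(dir, "genes.tsv")
    cells_f <- file.path(dir, "barcodes.tsv")
    if (file.exists(genes_f)) {
      ids <- utils::read.delim(genes_f, header = FALSE)[[1]]
      if (length(ids) != nrow(m))
        stop("read_matrix: genes.tsv has ", length(ids), " entries but matrix has ",
             nrow(m), " rows")
      rownames(m) <- ids
    } else rownames(m) <- sprintf("Gene%d", seq_len(nrow(m)))
    if (file.exists(cells_f)) {
      ids <- utils::read.delim(cells_f, header = FALSE)[[1]]
      if (length(ids) != ncol(m))
        stop("read_matrix: barcodes.tsv has ", length(ids), " entries but matrix has ",
             ncol(m), " columns")
      colnames(m) <- ids
    } else colnames(m) <- sprintf("Cell%d", seq_len(ncol(m)))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
  }
  if (orientation == "cell_by_gene") m <- t(m)
  m
}

#' Write an expression matrix to MTX or delimited text
#'
#' Mirror of [read_matrix()]. MTX output writes `genes.tsv` and
#' `barcodes.tsv` alongside. Output ordering is deterministic (row-major as
#' stored; genes then cells ascending in the sparse triplet).
#'
#' @param x gene x cell matrix (dense or sparse) or a `cci_norm`/`cci_imputed`.
#' @param path output path.
#' @param format `"auto"`, `"mtx"`, `"csv"`, or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, format = c("auto", "mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (inherits(x, "cci_norm") || inherits(x, "cci_imputed")) x <- x$values
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv",
                     stop("write_matrix: cannot infer format from extension of ", path))
  if (is.null(rownames(x))) rownames(x) <- sprintf("Gene%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("Cell%d", seq_len(ncol(x)))
  if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(x, "CsparseMatrix"), "generalMatrix"), path)
    dir <- dirname(path)
    utils::write.table(rownames(x), file.path(dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(colnames(x), file.path(dir, "barcodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    x <- as.matrix(x)
    df <- data.frame(gene = rownames(x), x, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML key/value configuration with optional `sim`, `cci`, `eval`, and `io`
#' sections; unspecified fields fall back to the package defaults, and the
#' parsed object echoes every effective value so a run can be reproduced
#' from its config alone.
#'
#' @param path YAML file.
#' @return list with `sim` (`sim_params`), `cci` (`cci_params`), `eval`
#'   (list of evaluation thresholds), `io` (passthrough list).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: no such file: ", path)
  raw <- yaml::read_yaml(path)
  sim <- do.call(sim_params, as.list(raw$sim %||% list()))
  cci <- do.call(cci_params, as.list(raw$cci %||% list()))
  eval_def <- list(alpha = 0.05, lfc_min = 0.2, snn_neighbors = 20,
                   snn_prune = 1 / 15)
  ev <- utils::modifyList(eval_def, as.list(raw$eval %||% list()))
  list(sim = sim, cci = cci, eval = ev, io = as.list(raw$io %||% list()))
}

#' Write a run configuration echo
#'
#' Serializes the effective configuration (every default filled in) so that
#' `read_run_config(write_run_config(cfg, path))` round-trips.
#'
#' @param config list as returned by [read_run_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  out <- list(sim = unclass(config$sim), cci = unclass(config$cci),
              eval = config$eval, io = config$io)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
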