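#' Expression matrix container
#'
#' Light wrapper around a genes x cells matrix carrying an ERCC spike-in mask
#' and a layer tag recording what the values are (raw counts, library-size
#' normalised, log-transformed, or kNN-imputed). All analysis functions in
#' the package consume and return this container or plain tibbles.
#'
#' @param values genes x cells numeric matrix (base or \pkg{Matrix} sparse)
#'   with unique row (gene) and column (cell) names.
#' @param ercc logical per-gene mask flagging spike-in rows, or `NULL` to
#'   detect rows whose name starts with `ercc_prefix`.
#' @param layer one of `"counts"`, `"normalized"`, `"log"`, `"imputed"`.
#' @param ercc_prefix gene-id prefix used when `ercc` is `NULL`.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, ercc = NULL, layer = "counts",
                        ercc_prefix = "ERCC-") {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_cf("expression matrix needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(values)))
    stop_cf("duplicate gene ids")
  if (anyDuplicated(colnames(values)))
    stop_cf("duplicate cell ids")
  layer <- match.arg(layer, c("counts", "normalized", "log", "imputed"))
  if (is.null(ercc)) ercc <- startsWith(rownames(values), ercc_prefix)
  stopifnot(length(ercc) == nrow(values))
  if (layer == "counts") {
    v <- if (methods::is(values, "sparseMatrix")) values@x else values
    if (any(v < 0) || any(v != floor(v)))
      stop_cf("counts layer must hold nonnegative integers")
  }
  structure(
    list(values = values, ercc = ercc, layer = layer),
    class = "expr_matrix"
  )
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer '%s', %d ERCC rows\n",
              nrow(x$values), ncol(x$values), x$layer, sum(x$ercc)))
  invisible(x)
}

#' Subset an expression matrix by genes and/or cells
#'
#' @param x an `expr_matrix`.
#' @param genes,cells character or logical/integer selectors; `NULL` keeps all.
#' @return An `expr_matrix` on the selection, same layer.
#' @export
subset_expr <- function(x, genes = NULL, cells = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(x$values)) else genes
  ci <- if (is.null(cells)) seq_len(ncol(x$values)) else cells
  if (is.character(gi)) gi <- match(gi, rownames(x$values))
  v <- x$values[gi, ci, drop = FALSE]
  ercc <- x$ercc[if (is.logical(gi)) which(gi) else gi]
  expr_matrix(v, ercc = ercc, layer = x$layer)
}

# dense numeric matrix of the values (internal)
expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) as.matrix(x$values) else as.matrix(x)
}
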