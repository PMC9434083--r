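#' Write a dataset directory
#'
#' Writes the count matrix as Matrix Market (`matrix.mtx`, 1-based per the
#' format) with `genes.tsv` / `cells.tsv` sidecars, plus optional
#' `embedding.tsv` (cells x dims), ground-truth tables, regulon activity
#' and marker sets JSON.
#'
#' @param counts an `expr_matrix` (counts layer).
#' @param dir output directory (created).
#' @param embedding optional cells x dims matrix.
#' @param truth optional `synthetic_truth`.
#' @param regulons optional `regulon_activity`.
#' @param markers optional named list of marker gene sets.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(counts, dir, embedding = NULL, truth = NULL,
                          regulons = NULL, markers = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(methods::as(counts$values, "dMatrix"), "TsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(
    data.frame(gene = rownames(counts$values), ercc = counts$ercc),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(data.frame(cell = colnames(counts$values)),
                     file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(embedding))
    utils::write.table(
      data.frame(cell = rownames(embedding), embedding,
                 check.names = FALSE),
      file.path(dir, "embedding.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.table(truth$cells, file.path(dir, "truth_cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(truth$genes))
      utils::write.table(truth$genes, file.path(dir, "truth_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(regulons)) {
    utils::write.table(
      data.frame(regulon = rownames(regulons$scores), regulons$scores,
                 check.names = FALSE),
      file.path(dir, "regulon_activity.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(regulons$tf_expr))
      utils::write.table(
        data.frame(regulon = rownames(regulons$tf_expr), regulons$tf_expr,
                   check.names = FALSE),
        file.path(dir, "tf_expression.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
  }
  if (!is.null(markers))
    jsonlite::write_json(markers, file.path(dir, "markers.json"))
  invisible(dir)
}

#' Load a dataset directory
#'
#' Reads a count matrix written as Matrix Market + sidecars (or a dense
#' `matrix.tsv` with gene rows and cell columns) and any optional
#' embedding, regulon activity, TF expression and marker sets present.
#' Sparse and dense inputs yield identical in-memory matrices. ERCC rows
#' are flagged from the `ercc` sidecar column when present, else by id
#' prefix.
#'
#' @param dir dataset directory as written by [write_dataset()].
#' @param ercc_prefix gene-id prefix marking spike-ins (default "ERCC-").
#' @return list: `counts` (`expr_matrix`) plus `embedding`, `regulons`,
#'   `markers` when present (`NULL` otherwise).
#' @export
load_dataset <- function(dir, ercc_prefix = "ERCC-") {
  mtx <- file.path(dir, "matrix.mtx")
  dense <- file.path(dir, "matrix.tsv")
  if (file.exists(mtx)) {
    genes_f <- file.path(dir, "genes.tsv")
    cells_f <- file.path(dir, "cells.tsv")
    for (f in c(mtx, genes_f, cells_f))
      if (!file.exists(f)) stop_cf(paste("missing file:", f))
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    genes <- utils::read.delim(genes_f)
    cells <- utils::read.delim(cells_f)
    if (anyDuplicated(cells$cell)) stop_cf("duplicate cell id in cells.tsv")
    if (anyDuplicated(genes$gene)) stop_cf("duplicate gene id in genes.tsv")
    if (nrow(m) != nrow(genes) || ncol(m) != nrow(cells))
      stop_cf(sprintf(
        "dimension mismatch: matrix.mtx is %d x %d but sidecars give %d genes, %d cells",
        nrow(m), ncol(m), nrow(genes), nrow(cells)))
    dimnames(m) <- list(genes$gene, cells$cell)
    ercc <- if ("ercc" %in% names(genes)) as.logical(genes$ercc)
            else startsWith(genes$gene, ercc_prefix)
  } else if (file.exists(dense)) {
    d <- utils::read.delim(dense, check.names = FALSE)
    m <- as.matrix(d[, -1])
    rownames(m) <- d[[1]]
    if (anyDuplicated(colnames(m))) stop_cf("duplicate cell id")
    ercc <- startsWith(rownames(m), ercc_prefix)
  } else stop_cf(paste("no matrix.mtx or matrix.tsv in", dir))
  counts <- expr_matrix(m, ercc = ercc, layer = "counts")
  read_opt <- function(f) if (file.exists(file.path(dir, f)))
    utils::read.delim(file.path(dir, f), check.names = FALSE) else NULL
  emb <- read_opt("embedding.tsv")
  if (!is.null(emb)) {
    rn <- emb[[1]]
    emb <- as.matrix(emb[, -1, drop = FALSE])
    rownames(emb) <- rn
  }
  reg <- read_opt("regulon_activity.tsv")
  regulons <- NULL
  if (!is.null(reg)) {
    scores <- as.matrix(reg[, -1]); rownames(scores) <- reg[[1]]
    tfe <- read_opt("tf_expression.tsv")
    tf_expr <- NULL
    if (!is.null(tfe)) {
      tf_expr <- as.matrix(tfe[, -1]); rownames(tf_expr) <- tfe[[1]]
    }
    regulons <- regulon_activity(scores, tf_expr = tf_expr)
  }
  markers <- NULL
  mk <- file.path(dir, "markers.json")
  if (file.exists(mk))
    markers <- lapply(jsonlite::read_json(mk), unlist)
  list(counts = counts, embedding = emb, regulons = regulons,
       markers = markers)
}
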