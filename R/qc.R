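#' QC thresholds for cell filtering
#'
#' Bounds on per-cell non-spike-in transcript totals, detected gene counts
#' and the ERCC read fraction. A cell passes when all three criteria hold.
#' Defaults use the deep-plate-protocol transcript bounds (5e4, 6e6), a
#' (1000, 10000) detected-gene interval and a 15% ERCC ceiling; scale the
#' gene bounds to the size of your gene panel.
#'
#' @param min_transcripts,max_transcripts non-ERCC transcript bounds.
#' @param min_genes,max_genes detected (count > 0) non-ERCC gene bounds.
#' @param max_ercc_fraction maximal ERCC fraction of total reads, in [0,1].
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_transcripts = 5e4, max_transcripts = 6e6,
                          min_genes = 1000, max_genes = 10000,
                          max_ercc_fraction = 0.15) {
  if (min_transcripts > max_transcripts || min_genes > max_genes)
    stop_cf("min must not exceed max")
  if (max_ercc_fraction < 0 || max_ercc_fraction > 1)
    stop_cf("max_ercc_fraction must be in [0,1]")
  structure(list(min_transcripts = min_transcripts,
                 max_transcripts = max_transcripts,
                 min_genes = min_genes, max_genes = max_genes,
                 max_ercc_fraction = max_ercc_fraction),
            class = "qc_thresholds")
}

#' Filter cells on transcript, gene and spike-in criteria
#'
#' A cell is kept iff its total non-ERCC transcripts lie in
#' `[min_transcripts, max_transcripts]`, its detected non-ERCC genes lie in
#' `[min_genes, max_genes]`, and its ERCC read fraction is at most
#' `max_ercc_fraction`.
#'
#' @param matrix an `expr_matrix` on the counts layer.
#' @param thresholds a [qc_thresholds()].
#' @return list with `kept` (cell ids) and `report`, a tibble with one row
#'   per cell: transcripts, genes, ercc_fraction, kept, reason (first failed
#'   criterion, or `""`).
#' @export
filter_cells <- function(matrix, thresholds = qc_thresholds()) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "counts")
    stop_cf("filter_cells needs the counts layer", "crestflow_layer_error")
  if (ncol(matrix$values) == 0) {
    warn("empty matrix: nothing to filter")
    return(list(kept = character(0), report = tibble::tibble(
      cell = character(0), transcripts = numeric(0), genes = integer(0),
      ercc_fraction = numeric(0), kept = logical(0), reason = character(0))))
  }
  v <- matrix$values
  total_ercc <- Matrix::colSums(v[matrix$ercc, , drop = FALSE])
  total_gene <- Matrix::colSums(v[!matrix$ercc, , drop = FALSE])
  genes <- Matrix::colSums(v[!matrix$ercc, , drop = FALSE] > 0)
  frac <- ifelse(total_ercc + total_gene > 0,
                 total_ercc / (total_ercc + total_gene), 0)
  th <- thresholds
  fail_tr <- total_gene < th$min_transcripts | total_gene > th$max_transcripts
  fail_g <- genes < th$min_genes | genes > th$max_genes
  fail_e <- frac > th$max_ercc_fraction
  kept <- !(fail_tr | fail_g | fail_e)
  reason <- rep("", length(kept))
  reason[fail_e] <- "ercc_fraction"
  reason[fail_g] <- "genes"
  reason[fail_tr] <- "transcripts"
  report <- tibble::tibble(cell = colnames(v), transcripts = total_gene,
                           genes = as.integer(genes), ercc_fraction = frac,
                           kept = kept, reason = reason)
  list(kept = colnames(v)[kept], report = report)
}

#' Library-size normalisation and log transform
#'
#' Scales each cell so its non-ERCC transcript total equals `target_sum`
#' (the scaling factor is applied to ERCC rows as well), then applies
#' `log(1 + x)` in base `log_base`. Zero-total cells are dropped with a
#' warning.
#'
#' @param matrix an `expr_matrix` on the counts layer.
#' @param target_sum per-cell target total (default 1e6).
#' @param log_base logarithm base (default 10).
#' @return An `expr_matrix` on the log layer.
#' @export
normalize_log <- function(matrix, target_sum = 1e6, log_base = 10) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$layer != "counts")
    stop_cf("normalize_log needs the counts layer", "crestflow_layer_error")
  v <- matrix$values
  totals <- Matrix::colSums(v[!matrix$ercc, , drop = FALSE])
  if (any(totals == 0)) {
    warn(sprintf("dropping %d zero-total cell(s)", sum(totals == 0)))
    v <- v[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  scaled <- as.matrix(v) %*% diag(target_sum / totals, length(totals))
  dimnames(scaled) <- list(rownames(v), colnames(v))
  out <- log1p(scaled) / log(log_base)
  expr_matrix(out, ercc = matrix$ercc, layer = "log")
}

#' Rank genes by excess dispersion
#'
#' Fits a quadratic trend of log variance versus log mean across genes on
#' the supplied (log-layer) matrix and ranks genes by positive residual
#' dispersion. Spike-in rows and zero-variance genes are never selected.
#'
#' @param matrix an `expr_matrix` (log layer recommended).
#' @param n_top number of genes to return.
#' @return tibble (gene, mean, variance, residual) sorted by descending
#'   residual; at most `min(n_top, genes with positive residual)` rows.
#' @export
select_overdispersed <- function(matrix, n_top = 100) {
  stopifnot(inherits(matrix, "expr_matrix"))
  v <- as.matrix(matrix$values[!matrix$ercc, , drop = FALSE])
  if (nrow(v) < 10) stop_cf("need at least 10 genes")
  m <- rowMeans(v)
  va <- row_vars(v)
  ok <- va > 0
  lm_ <- log10(m[ok] + 1e-8)
  lv <- log10(va[ok])
  fit <- stats::lm(lv ~ stats::poly(lm_, 2))
  resid <- lv - stats::fitted(fit)
  tb <- tibble::tibble(gene = rownames(v)[ok], mean = m[ok],
                       variance = va[ok], residual = resid)
  tb <- dplyr::arrange(dplyr::filter(tb, resid > 0), dplyr::desc(residual))
  if (n_top > nrow(tb))
    warn(sprintf("only %d genes with positive residual dispersion", nrow(tb)))
  utils::head(tb, n_top)
}

#' Build a cell kNN graph
#'
#' Symmetric k-nearest-neighbour adjacency over cells from a low-dimensional
#' embedding (euclidean distance), with unit edge weights. Used for kNN
#' smoothing and for community detection during annotation.
#'
#' @param embedding cells x dims matrix with cell rownames.
#' @param k neighbours per cell.
#' @return sparse symmetric adjacency (cells x cells).
#' @export
build_knn_graph <- function(embedding, k = 15) {
  n <- nrow(embedding)
  if (k >= n) stop_cf("k must be < number of cells")
  d2 <- cross_dist2(embedding, embedding)
  diag(d2) <- Inf
  idx <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                              x = 1, dims = c(n, n),
                              dimnames = list(rownames(embedding),
                                              rownames(embedding)))
  adj <- adj + Matrix::t(adj)  # symmetrise; collapse doubled edges to 1
  adj <- methods::as(adj, "CsparseMatrix")
  adj@x <- rep(1, length(adj@x))
  adj
}

#' Diffusion-style kNN smoothing of expression
#'
#' Replaces each cell's profile by the average of its graph neighbourhood,
#' iterated `steps` times: `imputed = X %*% t(P)^steps` where `P` is the
#' row-normalised adjacency with a self-loop added. `steps = 0` is the
#' identity. Linear in the expression values by construction.
#'
#' @param matrix an `expr_matrix`.
#' @param neighbor_graph cells x cells adjacency with nonnegative weights
#'   (e.g. from [build_knn_graph()]), same cells as `matrix`.
#' @param steps diffusion steps (>= 0).
#' @return An `expr_matrix` on the imputed layer.
#' @export
knn_smooth <- function(matrix, neighbor_graph, steps = 3) {
  stopifnot(inherits(matrix, "expr_matrix"), steps >= 0)
  v <- as.matrix(matrix$values)
  n <- ncol(v)
  if (nrow(neighbor_graph) != n || ncol(neighbor_graph) != n)
    stop_cf("neighbor graph dimensions do not match the cells")
  if (steps == 0)
    return(expr_matrix(v, ercc = matrix$ercc, layer = "imputed"))
  a <- neighbor_graph + Matrix::Diagonal(n)
  rs <- Matrix::rowSums(a)
  if (any(Matrix::rowSums(neighbor_graph) == 0))
    warn("disconnected cell(s): self-loop only")
  p <- Matrix::Diagonal(x = 1 / rs) %*% a
  out <- v
  for (s in seq_len(steps)) out <- out %*% Matrix::t(p)
  out <- as.matrix(out)
  dimnames(out) <- dimnames(v)
  expr_matrix(out, ercc = matrix$ercc, layer = "imputed")
}
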