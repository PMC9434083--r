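#' Correlation kNN graph from query samples to reference cells
#'
#' Computes the Pearson correlation of every query profile against every
#' reference cell over their shared features (minus an optional exclusion
#' list, e.g. cell-cycle-correlated genes supplied by the caller), keeps
#' the top `k` reference cells per query, and converts their correlations
#' to nonnegative weights summing to 1 (correlations shifted by the minimum
#' neighbour correlation plus a small epsilon, then normalised).
#'
#' @param query feature x sample matrix (or `expr_matrix`).
#' @param reference feature x cell matrix (or `expr_matrix`).
#' @param k neighbours per query (default 5).
#' @param exclude_genes optional genes removed before correlation.
#' @return A `transfer_graph` tibble: query, neighbor, correlation, weight;
#'   attributes record k and the shared gene set size.
#' @export
correlation_knn <- function(query, reference, k = 5, exclude_genes = NULL) {
  q <- feature_matrix(query)
  r <- feature_matrix(reference)
  shared <- setdiff(intersect(rownames(q), rownames(r)),
                    exclude_genes %||% character(0))
  if (length(shared) < 50)
    stop_cf(sprintf("only %d shared features after intersection/exclusion (need >= 50)",
                    length(shared)))
  cors <- suppressWarnings(stats::cor(q[shared, , drop = FALSE],
                                      r[shared, , drop = FALSE]))
  cors[is.na(cors)] <- -1
  eps <- 1e-6
  out <- purrr::map_dfr(seq_len(nrow(cors)), function(i) {
    nb <- order(cors[i, ], decreasing = TRUE)[seq_len(k)]
    cc <- cors[i, nb]
    w <- cc - min(cc) + eps
    tibble::tibble(query = rownames(cors)[i], neighbor = colnames(cors)[nb],
                   correlation = unname(cc), weight = unname(w / sum(w)))
  })
  attr(out, "k") <- k
  attr(out, "n_shared") <- length(shared)
  class(out) <- c("transfer_graph", class(out))
  out
}

#' Project queries into the reference embedding and transfer annotations
#'
#' Projected coordinates and transferred continuous values (e.g.
#' pseudotime) are the weight-weighted averages over each query's reference
#' neighbours; the transferred label is the label with maximal summed
#' weight (ties resolved lexicographically and flagged). Projections lie in
#' the convex hull of the neighbour coordinates by construction.
#'
#' @param graph a `transfer_graph` from [correlation_knn()].
#' @param reference_coords cells x dims matrix with cell rownames.
#' @param reference_labels optional named per-cell labels.
#' @param reference_values optional named per-cell numeric values.
#' @return tibble: query, one `coord_<dim>` column per dimension, and
#'   (when supplied) label, label_tied, value.
#' @export
project_and_propagate <- function(graph, reference_coords,
                                  reference_labels = NULL,
                                  reference_values = NULL) {
  gr <- tibble::as_tibble(graph)
  missing <- setdiff(gr$neighbor, rownames(reference_coords))
  if (length(missing)) stop_cf("coords missing for some neighbours")
  dims <- colnames(reference_coords) %||%
    paste0("dim", seq_len(ncol(reference_coords)))
  purrr::map_dfr(split(gr, gr$query), function(d) {
    w <- d$weight
    coords <- colSums(reference_coords[d$neighbor, , drop = FALSE] * w)
    row <- tibble::tibble(query = d$query[1])
    for (j in seq_along(dims)) row[[paste0("coord_", dims[j])]] <- coords[j]
    if (!is.null(reference_labels)) {
      lw <- tapply(w, reference_labels[d$neighbor], sum)
      top <- max(lw)
      winners <- sort(names(lw)[lw == top])
      row$label <- winners[1]
      row$label_tied <- length(winners) > 1
    }
    if (!is.null(reference_values))
      row$value <- sum(w * reference_values[d$neighbor])
    row
  })
}
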