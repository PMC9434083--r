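#' Regulon-activity container
#'
#' Regulon x cell activity scores in [0, 1] (AUC-style target-recovery
#' scores from an upstream regulon-inference pipeline), together with the
#' regulon-to-TF map and the TF expression per cell on the log10 scale used
#' for weighting.
#'
#' @param scores regulons x cells numeric matrix, values in [0, 1], with
#'   regulon rownames and cell colnames.
#' @param tf_map named character vector regulon -> TF name.
#' @param tf_expr regulons x cells matrix of the mapped TF's log10
#'   expression (same dimnames as `scores`), or `NULL` if unavailable.
#' @param weighted has TF weighting been applied already?
#' @param truth_cluster optional named per-regulon ground-truth cluster
#'   labels (synthetic data).
#' @return A `regulon_activity`.
#' @export
regulon_activity <- function(scores, tf_map = NULL, tf_expr = NULL,
                             weighted = FALSE, truth_cluster = NULL) {
  scores <- as.matrix(scores)
  if (any(scores < 0 | scores > 1)) stop_cf("scores must lie in [0, 1]")
  if (is.null(rownames(scores)))
    stop_cf("scores need regulon rownames")
  structure(list(scores = scores, tf_map = tf_map, tf_expr = tf_expr,
                 weighted = weighted, truth_cluster = truth_cluster),
            class = "regulon_activity")
}

#' @export
print.regulon_activity <- function(x, ...) {
  cat(sprintf("<regulon_activity> %d regulons x %d cells%s\n",
              nrow(x$scores), ncol(x$scores),
              if (x$weighted) ", TF-weighted" else ""))
  invisible(x)
}

#' Weight regulon activity by TF expression
#'
#' Per cell and regulon, the weight is the mapped TF's log10 expression
#' clamped to [0, 1] — i.e. the weight equals the log10 value between 0 and
#' 1 and is set to 1 when log10 expression exceeds 1 — and the weighted
#' score is `weight * score`. Regulons without TF expression pass through
#' unweighted (logged via warning). Weighting never increases a score and
#' is idempotent when all weights are 1.
#'
#' @param activity a `regulon_activity` with `tf_expr` present.
#' @return A weighted `regulon_activity`.
#' @export
weight_auc_by_tf <- function(activity) {
  stopifnot(inherits(activity, "regulon_activity"))
  if (is.null(activity$tf_expr))
    stop_cf("tf_expr is required for weighting")
  scores <- activity$scores
  have <- rownames(scores) %in% rownames(activity$tf_expr)
  if (any(!have))
    warn(sprintf("no TF expression for %d regulon(s): passed through",
                 sum(!have)))
  w <- pmin(pmax(activity$tf_expr[rownames(scores)[have], , drop = FALSE],
                 0), 1)
  scores[have, ] <- w * scores[have, , drop = FALSE]
  out <- activity
  out$scores <- scores
  out$weighted <- TRUE
  out
}

# cosine similarity between rows
cosine_similarity <- function(m) {
  norm <- sqrt(rowSums(m^2))
  norm[norm == 0] <- 1
  tcrossprod(m / norm)
}

#' Cluster fitted regulon trends into metaregulons
#'
#' Z-scores each regulon's fitted activity trend, builds a k-nearest-
#' neighbour graph under cosine distance, and partitions it with seeded
#' modularity-based (Leiden-style) community detection. A metaregulon's
#' trend is the unweighted arithmetic mean of its member regulons' (input,
#' unscaled) trends. Cluster labels are reordered by the mean activation
#' pseudotime (trend centre of mass) for stable reporting.
#'
#' @param trends regulons x grid matrix of fitted trends, or a
#'   `fitted_trend` tibble from [fit_trends()] (single segment, or segments
#'   concatenated in grid order).
#' @param n_neighbors kNN size (default 40; reduced with a warning when it
#'   reaches the number of regulons).
#' @param resolution community-detection resolution (default 2: on a
#'   similarity-weighted cosine graph over tens of regulons, unit
#'   resolution merges moderately correlated trend groups).
#' @param seed integer seed.
#' @return A `metaregulon_clustering`: tibble `clusters` (regulon,
#'   cluster), matrix `metaregulon_trends` (cluster x grid), the grid, and
#'   parameters.
#' @export
cluster_metaregulons <- function(trends, n_neighbors = 40, resolution = 2,
                                 seed = 1) {
  tm <- trend_matrix(trends)
  n <- nrow(tm$m)
  if (n < 2) stop_cf("need at least 2 regulon trends")
  k <- n_neighbors
  if (k >= n) {
    warn(sprintf("n_neighbors reduced to %d", n - 1))
    k <- n - 1
  }
  z <- t(scale(t(tm$m)))
  z[is.na(z)] <- 0  # flat trends scale to zero vectors
  sim <- cosine_similarity(z)
  diag(sim) <- -Inf
  # kNN edges weighted by (nonnegative) cosine similarity, so community
  # detection can separate clusters even when k saturates the graph
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(sim[i, ], decreasing = TRUE)[seq_len(k)]
    adj[i, nb] <- pmax(sim[i, nb], 0)
  }
  adj <- pmax(adj, t(adj))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  member <- igraph::membership(comm)
  # order cluster labels by mean trend centre of mass along the grid
  grid <- tm$grid
  com <- vapply(seq_len(n), function(i) {
    w <- tm$m[i, ] - min(tm$m[i, ])
    if (sum(w) == 0) return(mean(grid))
    sum(grid * w) / sum(w)
  }, numeric(1))
  cl_com <- tapply(com, member, mean)
  relabel <- match(as.character(member),
                   names(sort(cl_com)))
  meta <- do.call(rbind, lapply(sort(unique(relabel)), function(cl)
    colMeans(tm$m[relabel == cl, , drop = FALSE])))
  rownames(meta) <- paste0("metaregulon_", sort(unique(relabel)))
  structure(list(
    clusters = tibble::tibble(regulon = rownames(tm$m), cluster = relabel),
    metaregulon_trends = meta, grid = grid,
    n_neighbors = k, resolution = resolution, metric = "cosine"),
    class = "metaregulon_clustering")
}

trend_matrix <- function(trends) {
  if (is.matrix(trends))
    return(list(m = trends,
                grid = as.numeric(colnames(trends) %||%
                                    seq_len(ncol(trends)))))
  tb <- tibble::as_tibble(trends)
  stopifnot(all(c("feature", "grid_t", "fitted") %in% names(tb)))
  tb <- dplyr::arrange(tb, .data$feature, .data$segment, .data$grid_t)
  wide <- tidyr::pivot_wider(tb, id_cols = "feature",
                             names_from = c("segment", "grid_t"),
                             values_from = "fitted")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$feature
  grid <- dplyr::distinct(tb[, c("segment", "grid_t")])$grid_t
  list(m = m, grid = grid)
}

#' @export
print.metaregulon_clustering <- function(x, ...) {
  cat(sprintf("<metaregulon_clustering> %d regulons in %d metaregulons (cosine, k=%d)\n",
              nrow(x$clusters), nrow(x$metaregulon_trends), x$n_neighbors))
  invisible(x)
}

#' Summarise features into pseudotime bins
#'
#' Averages each feature over equal-width pseudotime bins — either global
#' bins across the whole trajectory (e.g. 20-bin trend heatmaps) or
#' `n_bins` bins within each tree segment (e.g. five bins per segment).
#' Empty bins are `NA`.
#'
#' @param values feature x cell matrix or `expr_matrix`.
#' @param pseudotime a `pseudotime_field`, `fork_path` or data frame with
#'   cell, t and (if `per_segment`) segment columns.
#' @param n_bins bins (global, or per segment).
#' @param per_segment bin within each segment instead of globally.
#' @return tibble: feature, segment (`"all"` when global), bin, t_center,
#'   mean, n_cells.
#' @export
bin_summaries <- function(values, pseudotime, n_bins = 20,
                          per_segment = FALSE) {
  y <- feature_matrix(values)
  pt <- as_pt_frame(pseudotime)
  y <- y[, pt$cell, drop = FALSE]
  if (n_bins > nrow(pt)) warn("more bins than cells: expect empty bins")
  groups <- if (per_segment) split(seq_len(nrow(pt)), pt$segment)
            else list(all = seq_len(nrow(pt)))
  purrr::map_dfr(names(groups), function(s) {
    idx <- groups[[s]]
    t_s <- pt$t[idx]
    breaks <- seq(min(t_s), max(t_s), length.out = n_bins + 1)
    bin <- pmin(findInterval(t_s, breaks, rightmost.closed = TRUE), n_bins)
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
    purrr::map_dfr(seq_len(n_bins), function(b) {
      members <- idx[bin == b]
      tibble::tibble(
        feature = rownames(y), segment = s, bin = b,
        t_center = centers[b],
        mean = if (length(members))
          unname(rowMeans(y[, pt$cell[members], drop = FALSE]))
          else NA_real_,
        n_cells = length(members))
    })
  })
}
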