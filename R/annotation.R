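#' Score cells against marker sets and assign cell types
#'
#' For each type, the score of a cell is the mean over that type's markers
#' of the gene's min-max-scaled (per gene, across cells) imputed
#' expression. A cell is labelled with the unique type whose score exceeds
#' its threshold; cells passing zero thresholds are unassigned with reason
#' `"no-type"`, cells passing two or more with reason `"multi-type"`
#' (discarded from annotation, as multi-type calls are ambiguous).
#'
#' @param imputed an `expr_matrix` (imputed layer recommended) or matrix.
#' @param marker_sets named list of marker gene vectors, one per type.
#' @param thresholds named numeric per-type score thresholds (scalar is
#'   recycled).
#' @param scaling `"minmax"` (default) or `"zscore"` per-gene scaling.
#' @return A `cell_annotation` tibble: cell, label (type or
#'   `"unassigned"`), reason (`""`, `"no-type"`, `"multi-type"`), and one
#'   `score_<type>` column per type.
#' @export
score_cell_types <- function(imputed, marker_sets, thresholds,
                             scaling = c("minmax", "zscore")) {
  scaling <- match.arg(scaling)
  if (!length(marker_sets) || any(!lengths(marker_sets)))
    stop_cf("every marker set must be non-empty")
  y <- feature_matrix(imputed)
  if (length(thresholds) == 1 && is.null(names(thresholds)))
    thresholds <- stats::setNames(rep(thresholds, length(marker_sets)),
                                  names(marker_sets))
  thresholds <- thresholds[names(marker_sets)]
  scores <- vapply(names(marker_sets), function(ty) {
    genes <- intersect(marker_sets[[ty]], rownames(y))
    missing <- setdiff(marker_sets[[ty]], rownames(y))
    if (length(missing))
      warn(sprintf("type %s: %d marker(s) absent, dropped", ty,
                   length(missing)))
    if (!length(genes)) return(rep(NA_real_, ncol(y)))
    sub <- y[genes, , drop = FALSE]
    scaled <- t(apply(sub, 1, function(g) {
      if (scaling == "minmax") {
        rng <- max(g) - min(g)
        if (rng == 0) rep(0, length(g)) else (g - min(g)) / rng
      } else {
        s <- stats::sd(g)
        if (s == 0) rep(0, length(g)) else (g - mean(g)) / s
      }
    }))
    colMeans(scaled)
  }, numeric(ncol(y)))
  passing <- t(t(scores) > thresholds)
  n_pass <- rowSums(passing, na.rm = TRUE)
  label <- rep("unassigned", ncol(y))
  reason <- rep("", ncol(y))
  one <- n_pass == 1
  label[one] <- colnames(passing)[apply(passing[one, , drop = FALSE], 1,
                                        which.max)]
  reason[n_pass == 0] <- "no-type"
  reason[n_pass >= 2] <- "multi-type"
  out <- tibble::tibble(cell = colnames(y), label = label, reason = reason)
  score_tb <- tibble::as_tibble(scores)
  names(score_tb) <- paste0("score_", names(marker_sets))
  out <- dplyr::bind_cols(out, score_tb)
  attr(out, "thresholds") <- thresholds
  attr(out, "scaling") <- scaling
  class(out) <- c("cell_annotation", class(out))
  out
}

#' Seeded community detection on a cell kNN graph
#'
#' Modularity-based (Leiden-style) partition of the cell kNN graph built
#' from an embedding, as used for hub detection.
#'
#' @param embedding cells x dims matrix with cell rownames.
#' @param k neighbours for the graph.
#' @param resolution community-detection resolution.
#' @param seed integer seed.
#' @return tibble: cell, cluster (integer labels).
#' @export
cluster_cells <- function(embedding, k = 15, resolution = 1, seed = 1) {
  adj <- build_knn_graph(embedding, k)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  tibble::tibble(cell = rownames(embedding),
                 cluster = as.integer(igraph::membership(comm)))
}

#' Detect the "hub" state from annotation and communities
#'
#' Flags every community whose fraction of unassigned cells is at least
#' `fraction_cutoff` (inclusive by default); the hub-cell mask is
#' membership in any flagged community. An empty hub is a valid result.
#'
#' @param annotation a `cell_annotation` (or tibble with cell and label).
#' @param communities tibble with columns cell, cluster covering the same
#'   cells.
#' @param fraction_cutoff unassigned-fraction cutoff (default 0.8).
#' @param inclusive use `>=` (default) rather than `>`.
#' @return A `hub_call`: tibble `clusters` (cluster, n, frac_unassigned,
#'   hub) and tibble `cells` (cell, cluster, hub).
#' @export
detect_hub <- function(annotation, communities, fraction_cutoff = 0.8,
                       inclusive = TRUE) {
  ann <- tibble::as_tibble(annotation)[, c("cell", "label")]
  d <- dplyr::inner_join(ann, tibble::as_tibble(communities), by = "cell")
  if (nrow(d) != nrow(ann))
    stop_cf("communities must cover all annotated cells")
  cl <- dplyr::summarise(
    dplyr::group_by(d, .data$cluster),
    n = dplyr::n(),
    frac_unassigned = mean(.data$label == "unassigned"),
    .groups = "drop")
  cl$hub <- if (inclusive) cl$frac_unassigned >= fraction_cutoff
            else cl$frac_unassigned > fraction_cutoff
  cells <- tibble::tibble(cell = d$cell, cluster = d$cluster,
                          hub = d$cluster %in% cl$cluster[cl$hub])
  structure(list(clusters = cl, cells = cells,
                 fraction_cutoff = fraction_cutoff, inclusive = inclusive),
            class = "hub_call")
}

#' @export
print.hub_call <- function(x, ...) {
  cat(sprintf("<hub_call> %d/%d clusters flagged hub (%d/%d cells) at cutoff %s%.2f\n",
              sum(x$clusters$hub), nrow(x$clusters), sum(x$cells$hub),
              nrow(x$cells), if (x$inclusive) ">=" else ">",
              x$fraction_cutoff))
  invisible(x)
}

#' Differential markers of the hub versus all other cells
#'
#' Two-sided Wilcoxon rank-sum test per gene comparing hub cells against
#' the rest on the supplied (normalised) expression, BH-corrected, ranked
#' with hub-elevated genes first by q-value. The effect is the difference
#' in means (positive = higher in hub).
#'
#' @param expr an `expr_matrix` (log/normalised layer) or matrix.
#' @param hub_mask logical per-cell mask (or a `hub_call`).
#' @param fdr significance cutoff recorded in the `significant` column.
#' @return tibble: gene, effect, p, q, significant, ranked.
#' @export
hub_markers <- function(expr, hub_mask, fdr = 0.05) {
  y <- feature_matrix(expr)
  if (inherits(hub_mask, "hub_call")) {
    mask <- hub_mask$cells$hub[match(colnames(y), hub_mask$cells$cell)]
  } else mask <- hub_mask
  if (sum(mask) < 3 || sum(!mask) < 3)
    stop_cf("both groups need at least 3 cells")
  res <- apply(y, 1, function(g) {
    if (max(g) == min(g)) return(c(0, 1))
    p <- suppressWarnings(
      stats::wilcox.test(g[mask], g[!mask], exact = FALSE)$p.value)
    c(mean(g[mask]) - mean(g[!mask]), if (is.finite(p)) p else 1)
  })
  out <- tibble::tibble(gene = rownames(y), effect = unname(res[1, ]),
                        p = unname(res[2, ]))
  out$q <- stats::p.adjust(out$p, "BH")
  out$significant <- out$q < fdr
  out <- dplyr::arrange(out, dplyr::desc(.data$effect > 0), .data$q,
                        dplyr::desc(abs(.data$effect)))
  out
}
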