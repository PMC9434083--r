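#' Define a gene module
#'
#' @param name module name.
#' @param genes non-empty character vector of gene ids.
#' @param branch optional branch label the module biases toward.
#' @return A `gene_module`.
#' @export
gene_module <- function(name, genes, branch = NA_character_) {
  if (!length(genes)) stop_cf("gene list must be non-empty")
  structure(list(name = name, genes = unique(genes), branch = branch),
            class = "gene_module")
}

#' Build pseudotime-ordered cell windows
#'
#' Sorts cells by pseudotime and cuts them into windows: `sliding` windows
#' of `window_size` cells advancing by `step` (count:
#' `floor((n - size) / step) + 1`), or `nonintersecting` consecutive
#' disjoint blocks of `window_size` (a final short block is kept when it
#' holds at least half a window).
#'
#' @param pseudotime a `pseudotime_field`, `fork_path`, or data frame with
#'   columns cell and t.
#' @param window_size cells per window.
#' @param step advance between sliding windows (ignored for
#'   nonintersecting).
#' @param scheme `"sliding"` or `"nonintersecting"`.
#' @return A `window_series` tibble: window, cells (list-column), n,
#'   t_center, t_min, t_max.
#' @export
make_windows <- function(pseudotime, window_size, step = NULL,
                         scheme = c("sliding", "nonintersecting")) {
  scheme <- match.arg(scheme)
  pt <- as_pt_frame(pseudotime)
  n <- nrow(pt)
  if (window_size > n) stop_cf("window_size exceeds the number of cells")
  if (window_size < 10) warn("window_size < 10: correlations are unstable")
  ord <- order(pt$t)
  cells <- pt$cell[ord]; t <- pt$t[ord]
  starts <- if (scheme == "sliding") {
    step <- step %||% max(1L, floor(window_size / 3))
    if (step < 1) stop_cf("step must be >= 1")
    seq(1, n - window_size + 1, by = step)
  } else seq(1, n, by = window_size)
  rows <- purrr::map_dfr(seq_along(starts), function(w) {
    i0 <- starts[w]
    i1 <- min(i0 + window_size - 1, n)
    if (scheme == "nonintersecting" && (i1 - i0 + 1) < window_size / 2)
      return(NULL)
    idx <- i0:i1
    tibble::tibble(window = w, cells = list(cells[idx]),
                   n = length(idx), t_center = stats::median(t[idx]),
                   t_min = t[i0], t_max = t[i1])
  })
  rows$window <- seq_len(nrow(rows))
  attr(rows, "scheme") <- scheme
  attr(rows, "window_size") <- window_size
  attr(rows, "step") <- if (scheme == "sliding") step else NA_integer_
  class(rows) <- c("window_series", class(rows))
  rows
}

#' Default window size for a trajectory of n cells
#'
#' `max(30, n / 20)` cells, with a step of a third of the window.
#'
#' @param n number of cells.
#' @return list with `window_size` and `step`.
#' @export
default_window_params <- function(n) {
  ws <- max(30, ceiling(n / 20))
  list(window_size = ws, step = max(1L, floor(ws / 3)))
}

# mean correlation over distinct unordered pairs within module genes
intra_mean <- function(cmat, genes) {
  g <- intersect(genes, rownames(cmat))
  if (length(g) < 2) return(NA_real_)
  sub <- cmat[g, g, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

inter_mean <- function(cmat, genes_a, genes_b) {
  ga <- intersect(genes_a, rownames(cmat))
  gb <- intersect(genes_b, rownames(cmat))
  if (!length(ga) || !length(gb)) return(NA_real_)
  mean(cmat[ga, gb, drop = FALSE])
}

#' Windowed intra- and inter-module correlations
#'
#' Within each window, computes the Pearson correlation matrix over the
#' module genes. Intra-module correlation is the mean over distinct
#' unordered gene pairs within a module; inter-module correlation the mean
#' over all cross-module pairs; the per-gene series is each gene's mean
#' correlation with the members of the opposing module. Genes constant
#' within a window are excluded from that window's pairs (and counted);
#' a window where everything is constant yields `NA`.
#'
#' @param expr feature x cell matrix or `expr_matrix`.
#' @param windows a `window_series`.
#' @param module_a,module_b disjoint [gene_module()]s present in `expr`.
#' @return A `window_correlations` tibble: window, t_center, intra_a,
#'   intra_b, inter, n_constant; attribute `gene_series` holds the per-gene
#'   cross-module series.
#' @export
window_module_correlations <- function(expr, windows, module_a, module_b) {
  y <- feature_matrix(expr)
  ga <- module_a$genes; gb <- module_b$genes
  if (length(intersect(ga, gb))) stop_cf("modules must be disjoint")
  missing <- setdiff(c(ga, gb), rownames(y))
  if (length(missing))
    stop_cf(paste("genes absent from the matrix:",
                  paste(missing, collapse = ", ")))
  gene_rows <- list()
  out <- purrr::map_dfr(seq_len(nrow(windows)), function(w) {
    cells <- windows$cells[[w]]
    if (length(cells) < 3) stop_cf("each window needs >= 3 cells")
    sub <- y[c(ga, gb), cells, drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    keep <- sds > 0
    n_const <- sum(!keep)
    if (sum(keep) < 2) {
      return(tibble::tibble(window = windows$window[w],
                            t_center = windows$t_center[w],
                            intra_a = NA_real_, intra_b = NA_real_,
                            inter = NA_real_, n_constant = n_const))
    }
    cmat <- stats::cor(t(sub[keep, , drop = FALSE]))
    gser <- tibble::tibble(
      window = windows$window[w],
      gene = rownames(cmat),
      vs_module = ifelse(rownames(cmat) %in% ga, module_b$name,
                         module_a$name),
      mean_cor = vapply(rownames(cmat), function(g) {
        other <- if (g %in% ga) intersect(gb, rownames(cmat))
                 else intersect(ga, rownames(cmat))
        if (!length(other)) return(NA_real_)
        mean(cmat[g, other])
      }, numeric(1)))
    gene_rows[[length(gene_rows) + 1]] <<- gser
    tibble::tibble(window = windows$window[w],
                   t_center = windows$t_center[w],
                   intra_a = intra_mean(cmat, ga),
                   intra_b = intra_mean(cmat, gb),
                   inter = inter_mean(cmat, ga, gb),
                   n_constant = n_const)
  })
  attr(out, "gene_series") <- dplyr::bind_rows(gene_rows)
  attr(out, "modules") <- c(module_a$name, module_b$name)
  class(out) <- c("window_correlations", class(out))
  out
}

#' Window correlations aggregated over probabilistic mappings
#'
#' Repeats the window-correlation analysis across hard cell-to-node
#' mappings sampled from the tree's soft assignment matrix: in each mapping
#' a path cell takes the pseudotime of its sampled node (sampling restricted
#' to the path's nodes), the windows are rebuilt on the new ordering, and
#' the per-window statistics are averaged. Reports mean and sd per window
#' index across mappings.
#'
#' @param expr feature x cell matrix or `expr_matrix`.
#' @param tree a `principal_tree`.
#' @param pseudotime a `pseudotime_field` for `tree`.
#' @param from,to milestone node ids passed to [extract_path()].
#' @param module_a,module_b [gene_module()]s.
#' @param n_mappings number of probabilistic mappings.
#' @param window_size,step,scheme window parameters ([make_windows()]).
#' @param seed integer seed.
#' @return tibble: window, statistic in intra_a/intra_b/inter, mean, sd,
#'   t_center (mean over mappings).
#' @export
correlations_over_mappings <- function(expr, tree, pseudotime, from, to,
                                       module_a, module_b, n_mappings = 100,
                                       window_size = NULL, step = NULL,
                                       scheme = "sliding", seed = 1) {
  path <- extract_path(tree, pseudotime, from, to)
  cells <- path$cells
  if (is.null(window_size))
    window_size <- default_window_params(nrow(cells))$window_size
  nodes <- unlist(path$node_sets[setdiff(names(path$node_sets), "fork")])
  rsub <- tree$R[cells$cell, nodes, drop = FALSE]
  rsub <- rsub / rowSums(rsub)
  sd_flag <- n_mappings < 2
  if (sd_flag) warn("n_mappings < 2: sd reported as 0")
  set.seed(seed)
  per_map <- lapply(seq_len(n_mappings), function(m) {
    node_pick <- nodes[vapply(seq_len(nrow(rsub)), function(i)
      sample.int(length(nodes), 1, prob = rsub[i, ]), integer(1))]
    pt <- tibble::tibble(cell = cells$cell,
                         t = pseudotime$node_t[node_pick], segment = "path")
    w <- make_windows(pt, window_size, step, scheme)
    window_module_correlations(expr, w, module_a, module_b)
  })
  n_win <- min(vapply(per_map, nrow, integer(1)))
  stacked <- dplyr::bind_rows(lapply(per_map, function(d)
    d[seq_len(n_win), c("window", "t_center", "intra_a", "intra_b",
                        "inter")]))
  long <- tidyr::pivot_longer(stacked, c("intra_a", "intra_b", "inter"),
                              names_to = "statistic", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$window, .data$statistic),
    t_center = mean(.data$t_center),
    mean = mean(.data$value, na.rm = TRUE),
    sd = if (sd_flag) 0 else stats::sd(.data$value, na.rm = TRUE),
    .groups = "drop")
  attr(out, "n_mappings") <- n_mappings
  attr(out, "fork_time") <- path$fork_time
  out
}
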