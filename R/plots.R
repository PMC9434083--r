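#' Plot a principal tree over its embedding
#'
#' @param tree a `principal_tree`.
#' @param embedding the cells x dims matrix the tree was fitted on (first
#'   two dimensions are drawn).
#' @param colour optional per-cell values to colour cells by.
#' @return a ggplot object.
#' @export
plot_tree <- function(tree, embedding, colour = NULL) {
  cells <- tibble::tibble(x = embedding[, 1], y = embedding[, 2])
  if (!is.null(colour)) cells$colour <- colour
  nodes <- tibble::tibble(x = tree$node_positions[, 1],
                          y = tree$node_positions[, 2])
  seg <- tibble::tibble(
    x = tree$node_positions[tree$edges[, 1], 1],
    y = tree$node_positions[tree$edges[, 1], 2],
    xend = tree$node_positions[tree$edges[, 2], 1],
    yend = tree$node_positions[tree$edges[, 2], 2])
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y)) +
    (if (is.null(colour)) ggplot2::geom_point(alpha = 0.4, size = 0.7)
     else ggplot2::geom_point(ggplot2::aes(colour = .data$colour),
                              alpha = 0.6, size = 0.7)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(xend = .data$xend,
                                       yend = .data$yend),
                          linewidth = 0.8) +
    ggplot2::geom_point(data = nodes, size = 1.4, shape = 21,
                        fill = "white") +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
  p
}

#' @export
autoplot.fitted_trend <- function(object, features = NULL, ...) {
  tb <- tibble::as_tibble(object)
  if (!is.null(features)) tb <- tb[tb$feature %in% features, ]
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$grid_t, y = .data$fitted,
                                   colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "pseudotime", y = "fitted expression") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.window_correlations <- function(object, fork_time = NULL, ...) {
  tb <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("intra_a", "intra_b", "inter"),
                            names_to = "statistic", values_to = "value")
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$t_center,
                                        y = .data$value,
                                        colour = .data$statistic)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "window pseudotime", y = "mean local correlation") +
    ggplot2::theme_minimal()
  if (!is.null(fork_time))
    p <- p + ggplot2::geom_vline(xintercept = fork_time, linetype = 3)
  p
}

#' @export
autoplot.metaregulon_clustering <- function(object, ...) {
  m <- object$metaregulon_trends
  tb <- tibble::tibble(
    metaregulon = rep(rownames(m), each = ncol(m)),
    grid_t = rep(object$grid, times = nrow(m)),
    activity = as.vector(t(m)))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$grid_t, y = .data$activity,
                                   colour = .data$metaregulon)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "pseudotime", y = "mean regulon activity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
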