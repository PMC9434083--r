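#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.assoc_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.assoc_result <- function(x, ...) {
  tibble::tibble(n_features = nrow(x), n_significant = sum(x$significant),
                 n_degenerate = sum(x$degenerate),
                 fdr_threshold = attr(x, "fdr_threshold"),
                 a_cut = attr(x, "a_cut"),
                 spline_df = attr(x, "spline_df"),
                 n_cells = attr(x, "n_cells"))
}

#' @export
tidy.fork_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.fork_result <- function(x, ...) {
  assigned <- !is.na(x$branch)
  tibble::tibble(n_tested = nrow(x), n_candidate = sum(x$candidate),
                 n_assigned = sum(assigned),
                 n_early = sum(x$timing == "early", na.rm = TRUE),
                 n_late = sum(x$timing == "late", na.rm = TRUE),
                 fork_time = attr(x, "fork_time"),
                 n_bins = attr(x, "n_bins"),
                 rate_threshold = attr(x, "rate_threshold"))
}

#' @export
tidy.metaregulon_clustering <- function(x, ...) x$clusters

#' @export
glance.metaregulon_clustering <- function(x, ...) {
  tibble::tibble(n_regulons = nrow(x$clusters),
                 n_metaregulons = nrow(x$metaregulon_trends),
                 n_neighbors = x$n_neighbors, resolution = x$resolution,
                 metric = x$metric)
}

#' @export
tidy.hub_call <- function(x, ...) x$clusters

#' @export
glance.hub_call <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 n_hub_clusters = sum(x$clusters$hub),
                 n_hub_cells = sum(x$cells$hub),
                 fraction_cutoff = x$fraction_cutoff,
                 inclusive = x$inclusive)
}

#' @export
tidy.principal_tree <- function(x, ...) {
  deg <- node_degrees(x)
  tibble::tibble(node = seq_len(nrow(x$node_positions)), degree = deg,
                 kind = dplyr::case_when(deg <= 1 ~ "tip", deg == 2 ~ "internal",
                                         TRUE ~ "fork"))
}

#' @export
glance.principal_tree <- function(x, ...) {
  deg <- node_degrees(x)
  tibble::tibble(n_nodes = nrow(x$node_positions), n_edges = nrow(x$edges),
                 n_tips = sum(deg == 1), n_forks = sum(deg >= 3),
                 sigma = x$sigma, lambda = x$lambda,
                 converged = x$converged, n_iter = x$n_iter,
                 final_objective = x$objective[length(x$objective)])
}
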