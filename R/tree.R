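#' Fit a principal tree (SimplePPT) to an embedding
#'
#' Alternates three steps until convergence: (1) soft assignment
#' `R[i,j] ∝ exp(-d(x_i, c_j)^2 / sigma)`, row-normalised; (2) tree edges =
#' minimum spanning tree over current node-node squared distances; (3) node
#' positions solving the regularised least-squares system minimising
#' `sum_ij R_ij d(x_i, c_j)^2 + lambda * sum_edges ||c_j - c_k||^2`.
#' Stops when the maximal node displacement drops below `tol` or after
#' `max_iter` iterations. Nodes are initialised by k-means++-style seeding
#' on the embedding under the given seed.
#'
#' @param embedding cells x dims numeric matrix with cell rownames.
#' @param n_nodes number of tree nodes (1 <= n_nodes <= cells).
#' @param sigma kernel bandwidth in squared-distance units; default
#'   `0.05 * median pairwise squared distance`.
#' @param lambda elastic penalty weight (>= 0); the large-atlas preset of
#'   the underlying method uses `sigma = 5e-4, lambda = 200` on diffusion
#'   coordinates — for desk-scale embeddings the defaults here are saner.
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @param max_iter,tol convergence controls.
#' @param seed integer seed for the node initialisation.
#' @return A `principal_tree`: node_positions, edges (2-column matrix), `R`
#'   (cells x nodes), sigma, lambda, root (unset), objective trace and
#'   convergence flag.
#' @export
fit_principal_tree <- function(embedding, n_nodes = 30, sigma = NULL,
                               lambda = 1, metric = "euclidean",
                               max_iter = 50, tol = 1e-4, seed = 1) {
  metric <- match.arg(metric, "euclidean")
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (n_nodes < 1) stop_cf("n_nodes must be >= 1")
  if (n_nodes > n) stop_cf("n_nodes must not exceed the number of cells")
  if (is.null(sigma)) {
    sub <- embedding[seq_len(min(n, 500)), , drop = FALSE]
    d2 <- cross_dist2(sub, sub)
    sigma <- 0.05 * stats::median(d2[upper.tri(d2)])
  }
  if (sigma <= 0) stop_cf("sigma must be > 0")
  if (lambda < 0) stop_cf("lambda must be >= 0")
  set.seed(seed)
  centers <- kmeanspp_init(embedding, n_nodes)
  if (n_nodes > 1) {
    km <- suppressWarnings(stats::kmeans(embedding, centers = centers,
                                         iter.max = 10))
    centers <- km$centers
  }
  edges <- matrix(integer(0), 0, 2)
  objective <- numeric(0)
  free_energy <- numeric(0)
  converged <- FALSE
  warned <- FALSE
  for (iter in seq_len(max_iter)) {
    d2 <- cross_dist2(embedding, centers)
    k <- exp(-(d2 - matrixStats_rowMins(d2)) / sigma)  # stabilised kernel
    rs <- rowSums(k)
    zero <- rs == 0 | !is.finite(rs)
    if (any(zero)) {
      if (!warned) {
        warn("kernel underflow for some cells: assigned to nearest node")
        warned <- TRUE
      }
      for (i in which(zero)) k[i, ] <- as.numeric(
        d2[i, ] == min(d2[i, ]))
      rs <- rowSums(k)
    }
    R <- k / rs
    edges <- mst_edges(centers)
    # data + elastic objective at current (R, edges, centers)
    elastic <- if (nrow(edges)) sum((centers[edges[, 1], , drop = FALSE] -
                                     centers[edges[, 2], , drop = FALSE])^2)
               else 0
    objective <- c(objective, sum(R * d2) + lambda * elastic)
    ent <- sum(R[R > 0] * log(R[R > 0]))
    free_energy <- c(free_energy, sum(R * d2) + sigma * ent + lambda * elastic)
    lap <- graph_laplacian(n_nodes, edges)
    lhs <- Matrix::Diagonal(x = colSums(R)) + lambda * lap
    rhs <- crossprod(R, embedding)
    new_centers <- as.matrix(Matrix::solve(lhs, rhs))
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    if (shift < tol) { converged <- TRUE; break }
  }
  d2 <- cross_dist2(embedding, centers)
  k <- exp(-(d2 - matrixStats_rowMins(d2)) / sigma)
  R <- k / rowSums(k)
  rownames(R) <- rownames(embedding)
  edges <- mst_edges(centers)
  rownames(centers) <- paste0("node_", seq_len(n_nodes))
  structure(list(node_positions = centers, edges = edges, R = R,
                 sigma = sigma, lambda = lambda, metric = metric,
                 root = NULL, objective = objective,
                 free_energy = free_energy,
                 converged = converged, n_iter = length(objective)),
            class = "principal_tree")
}

matrixStats_rowMins <- function(m) apply(m, 1, min)

# k-means++ style seeding (distance-proportional sampling)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  if (k == 1) return(matrix(colMeans(x), 1, ncol(x)))
  idx <- sample.int(n, 1)
  for (j in seq_len(k - 1)) {
    d2 <- matrixStats_rowMins(cross_dist2(x, x[idx, , drop = FALSE]))
    d2[idx] <- 0
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- c(idx, sample.int(n, 1, prob = p))
  }
  x[idx, , drop = FALSE]
}

mst_edges <- function(centers) {
  k <- nrow(centers)
  if (k == 1) return(matrix(integer(0), 0, 2))
  d2 <- cross_dist2(centers, centers)
  g <- igraph::graph_from_adjacency_matrix(d2, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  m <- igraph::mst(g)
  el <- igraph::as_edgelist(m, names = FALSE)
  el <- t(apply(el, 1, sort))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

graph_laplacian <- function(k, edges) {
  if (!nrow(edges))
    return(Matrix::Matrix(0, k, k, sparse = TRUE))
  a <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = 1, dims = c(k, k))
  Matrix::Diagonal(x = Matrix::rowSums(a)) - a
}

#' @export
print.principal_tree <- function(x, ...) {
  deg <- node_degrees(x)
  cat(sprintf(paste0("<principal_tree> %d nodes, %d edges, %d tips, ",
                     "%d forks; sigma=%.3g lambda=%.3g; %s in %d iter\n"),
              nrow(x$node_positions), nrow(x$edges), sum(deg == 1),
              sum(deg >= 3), x$sigma, x$lambda,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

tree_igraph <- function(tree) {
  k <- nrow(tree$node_positions)
  if (!nrow(tree$edges))
    return(igraph::make_empty_graph(k, directed = FALSE))
  w <- sqrt(rowSums((tree$node_positions[tree$edges[, 1], , drop = FALSE] -
                     tree$node_positions[tree$edges[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(tree$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, k - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  g
}

node_degrees <- function(tree) {
  k <- nrow(tree$node_positions)
  deg <- integer(k)
  if (nrow(tree$edges)) {
    tb <- table(factor(c(tree$edges[, 1], tree$edges[, 2]), levels = 1:k))
    deg <- as.integer(tb)
  }
  deg
}

# per-node segment ids: segments are maximal milestone-to-milestone paths.
# Walk the tree from the root; entering a child of a milestone opens a new
# segment. The root node takes the segment of its first child edge.
node_segments <- function(tree, root) {
  g <- tree_igraph(tree)
  k <- nrow(tree$node_positions)
  deg <- node_degrees(tree)
  milestone <- deg == 1 | deg >= 3
  seg <- integer(k)
  seg_count <- 0
  parent <- rep(NA_integer_, k)
  order_bfs <- igraph::bfs(g, root, father = TRUE)
  parent_v <- as.integer(order_bfs$father)
  for (v in as.integer(order_bfs$order)) {
    p <- parent_v[v]
    if (is.na(p)) next
    seg[v] <- if (milestone[p] && seg[p] != 0) seg_count + 1 else seg[p]
    if (milestone[p] && seg[p] != 0) seg_count <- seg_count + 1
    if (seg[v] == 0) { seg_count <- seg_count + 1; seg[v] <- seg_count }
    parent[v] <- p
  }
  if (k == 1) seg[1] <- 1
  if (seg[root] == 0 && k > 1) {
    child <- which(parent == root)[1]
    seg[root] <- seg[child]
  }
  list(segment = seg, parent = parent, milestone = milestone)
}

#' Compute pseudotime from a rooted principal tree
#'
#' Node pseudotime is the geodesic distance from the root along tree edges
#' (edge length = embedding distance between its endpoint nodes). Cell
#' pseudotime is either the R-weighted mean of node pseudotimes (`soft`) or
#' the pseudotime of the cell's maximum-responsibility node (`hard`; ties
#' broken toward the lower node id). The cell's segment is that of its
#' maximum-responsibility node.
#'
#' @param tree a `principal_tree`.
#' @param root root node id (integer index).
#' @param mode `"soft"` or `"hard"` projection of node pseudotime to cells.
#' @return A `pseudotime_field`: tibble `cells` (cell, t, segment, node),
#'   per-node pseudotime `node_t`, per-node segment, the root, and the tree.
#' @export
compute_pseudotime <- function(tree, root = NULL, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  root <- root %||% tree$root
  if (is.null(root))
    stop_cf("no root set: pass `root` or use select_root() first")
  k <- nrow(tree$node_positions)
  if (root < 1 || root > k) stop_cf("root is not a tree node")
  g <- tree_igraph(tree)
  node_t <- as.numeric(igraph::distances(g, v = root))
  segs <- node_segments(tree, root)
  best <- max.col(tree$R, ties.method = "first")  # lower id wins ties
  t_cell <- if (mode == "soft") as.numeric(tree$R %*% node_t)
            else node_t[best]
  structure(list(
    cells = tibble::tibble(cell = rownames(tree$R), t = t_cell,
                           segment = segs$segment[best], node = best),
    node_t = node_t, node_segment = segs$segment,
    node_parent = segs$parent, root = root, mode = mode, tree = tree
  ), class = "pseudotime_field")
}

#' @export
print.pseudotime_field <- function(x, ...) {
  cat(sprintf("<pseudotime_field> %d cells, root node %d, mode %s, t in [%.3g, %.3g]\n",
              nrow(x$cells), x$root, x$mode, min(x$cells$t), max(x$cells$t)))
  invisible(x)
}

#' Pick a root tip by an external per-cell score
#'
#' Root choice is a biological judgment (e.g. developmental stage or a
#' differentiation-potential score); this helper selects the tip whose
#' assigned cells maximise the mean of a user-supplied per-cell score.
#'
#' @param tree a `principal_tree`.
#' @param cell_score numeric per-cell score, aligned with rows of `tree$R`.
#' @return root node id (integer).
#' @export
select_root <- function(tree, cell_score) {
  deg <- node_degrees(tree)
  tips <- which(deg <= 1)
  best <- max.col(tree$R, ties.method = "first")
  tip_score <- vapply(tips, function(v) {
    cells <- best == v
    if (!any(cells)) return(-Inf)
    mean(cell_score[cells])
  }, numeric(1))
  tips[which.max(tip_score)]
}

#' Sample hard cell-to-node mappings from the soft assignment
#'
#' Each mapping draws, independently per cell, one node with probabilities
#' given by the cell's row of `R`. Used to propagate assignment uncertainty
#' into downstream statistics.
#'
#' @param tree a `principal_tree`.
#' @param n_mappings number of mappings.
#' @param seed integer seed; identical seeds give identical mappings.
#' @return integer matrix cells x n_mappings of node ids.
#' @export
probabilistic_mappings <- function(tree, n_mappings = 100, seed = 1) {
  set.seed(seed)
  k <- ncol(tree$R)
  out <- t(apply(tree$R, 1, function(p)
    sample.int(k, n_mappings, replace = TRUE, prob = p)))
  if (n_mappings == 1) out <- matrix(out, ncol = 1)
  rownames(out) <- rownames(tree$R)
  out
}

#' Identify milestones (tips and forks) and assign cells to them
#'
#' Milestones are tree nodes of degree 1 (tips) or degree >= 3 (forks).
#' Each cell is assigned to the nearer, in pseudotime, of the two milestones
#' bounding its segment; ties go to the earlier milestone.
#'
#' @param tree a `principal_tree`.
#' @param pseudotime a `pseudotime_field` for this tree.
#' @return list: `milestones` tibble (node, kind, t) and `cells` tibble
#'   (cell, milestone).
#' @export
identify_milestones <- function(tree, pseudotime) {
  deg <- node_degrees(tree)
  k <- nrow(tree$node_positions)
  ms_nodes <- which(deg == 1 | deg >= 3)
  if (k == 1) ms_nodes <- 1L
  kind <- ifelse(deg[ms_nodes] >= 3, "fork", "tip")
  if (k == 1) kind <- "tip"
  ms <- tibble::tibble(node = ms_nodes, kind = kind,
                       t = pseudotime$node_t[ms_nodes])
  g <- tree_igraph(tree)
  root <- pseudotime$root
  # root path per milestone, computed once
  ms_paths <- lapply(ms_nodes, function(m)
    as.integer(igraph::shortest_paths(g, root, m)$vpath[[1]]))
  # candidate milestones per tree node (those on the node's own root-to-tip
  # paths): milestones upstream of the node plus milestones downstream of it
  candidates_for <- function(v) {
    path_v <- as.integer(igraph::shortest_paths(g, root, v)$vpath[[1]])
    up <- intersect(path_v, ms_nodes)
    below <- ms_nodes[vapply(ms_paths, function(p) v %in% p, logical(1))]
    unique(c(up, below))
  }
  uniq_nodes <- unique(pseudotime$cells$node)
  cand <- stats::setNames(lapply(uniq_nodes, candidates_for),
                          uniq_nodes)
  cells <- pseudotime$cells
  ms_cell <- vapply(seq_len(nrow(cells)), function(i) {
    path_ms <- cand[[as.character(cells$node[i])]]
    d <- abs(cells$t[i] - pseudotime$node_t[path_ms])
    tied <- path_ms[d == min(d)]
    tied[which.min(pseudotime$node_t[tied])]  # tie -> earlier milestone
  }, integer(1))
  list(milestones = ms,
       cells = tibble::tibble(cell = cells$cell, milestone = ms_cell))
}

#' Extract the cells on a root-to-tip path or a two-branch fork subtree
#'
#' With one target milestone, returns every cell whose maximum-
#' responsibility node lies on the source-to-target path (branch label
#' `"path"`). With two targets, the two paths must share a unique fork;
#' cells are labelled `"pre-fork"`, `"branch-1"` or `"branch-2"` by the
#' position of their node, and the fork node's pseudotime is reported.
#'
#' @param tree a `principal_tree`.
#' @param pseudotime a `pseudotime_field`.
#' @param from source milestone node id (typically the root or a fork).
#' @param to one or two target milestone node ids downstream of `from`.
#' @return A `fork_path`: tibble `cells` (cell, t, branch, node),
#'   `fork_time` (two targets) and the node sets per label.
#' @export
extract_path <- function(tree, pseudotime, from, to) {
  g <- tree_igraph(tree)
  paths <- lapply(to, function(m)
    as.integer(igraph::shortest_paths(g, from, m)$vpath[[1]]))
  if (any(lengths(paths) == 0)) stop_cf("target not reachable from source")
  if (length(to) == 1) {
    nodes <- paths[[1]]
    lab <- stats::setNames(rep("path", length(nodes)), nodes)
    fork_time <- NA_real_
    node_sets <- list(path = nodes)
  } else if (length(to) == 2) {
    shared <- intersect(paths[[1]], paths[[2]])
    # fork = last shared node along path 1
    fork <- shared[which.max(match(shared, paths[[1]]))]
    b1 <- setdiff(paths[[1]], shared)
    b2 <- setdiff(paths[[2]], shared)
    if (!length(b1) || !length(b2))
      stop_cf("the two targets do not define a fork downstream of `from`")
    nodes <- c(shared, b1, b2)
    lab <- stats::setNames(c(rep("pre-fork", length(shared)),
                             rep("branch-1", length(b1)),
                             rep("branch-2", length(b2))), nodes)
    fork_time <- pseudotime$node_t[fork]
    node_sets <- list(`pre-fork` = shared, `branch-1` = b1, `branch-2` = b2,
                      fork = fork)
  } else stop_cf("`to` must name one or two milestones")
  cells <- pseudotime$cells
  keep <- cells$node %in% nodes
  out <- cells[keep, c("cell", "t", "node")]
  out$branch <- unname(lab[as.character(out$node)])
  structure(list(cells = out[, c("cell", "t", "branch", "node")],
                 fork_time = fork_time, node_sets = node_sets,
                 from = from, to = to, pseudotime = pseudotime),
            class = "fork_path")
}

#' @export
print.fork_path <- function(x, ...) {
  cat(sprintf("<fork_path> %d cells (%s)%s\n", nrow(x$cells),
              paste(names(table(x$cells$branch)), table(x$cells$branch),
                    sep = ":", collapse = ", "),
              if (!is.na(x$fork_time))
                sprintf(", fork at t=%.3g", x$fork_time) else ""))
  invisible(x)
}
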