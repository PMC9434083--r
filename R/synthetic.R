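#' Branching-topology specification
#'
#' Defines a rooted tree of trajectory segments in embedding space. Each
#' segment has a pseudotime length and a unit direction vector; cells are
#' later placed uniformly along segment arc-length, so pseudotime and
#' arc-length coincide.
#'
#' @param segments tibble/data.frame with columns `segment` (id), `parent`
#'   (parent segment id or `NA` for the root), `length` (> 0 pseudotime
#'   span), `direction` (list-column of numeric vectors, one per segment,
#'   all the same dimension), `fraction` (cell allocation, summing to 1).
#' @return A validated `topology_spec`.
#' @export
topology_spec <- function(segments) {
  segments <- tibble::as_tibble(segments)
  need <- c("segment", "parent", "length", "direction", "fraction")
  if (!all(need %in% names(segments)))
    stop_cf(paste("topology needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(segments$segment)) stop_cf("duplicate segment ids")
  roots <- which(is.na(segments$parent))
  if (length(roots) != 1) stop_cf("exactly one root segment required")
  if (any(segments$length <= 0)) stop_cf("segment lengths must be > 0")
  if (!all(stats::na.omit(segments$parent) %in% segments$segment))
    stop_cf("unknown parent segment")
  dims <- lengths(segments$direction)
  if (length(unique(dims)) != 1)
    stop_cf("direction vectors have inconsistent dimensions")
  if (abs(sum(segments$fraction) - 1) > 1e-8)
    stop_cf("allocation fractions must sum to 1")
  # reject cycles: walking to the root must terminate from every segment
  for (s in segments$segment) {
    seen <- character(); cur <- s
    while (!is.na(cur)) {
      if (cur %in% seen) stop_cf("segments do not form a rooted tree")
      seen <- c(seen, cur)
      cur <- segments$parent[match(cur, segments$segment)]
    }
  }
  structure(list(segments = segments, dims = dims[1]), class = "topology_spec")
}

# pseudotime at which a segment starts (sum of ancestor lengths)
segment_start_times <- function(topology) {
  seg <- topology$segments
  start <- stats::setNames(numeric(nrow(seg)), seg$segment)
  for (s in seg$segment) {
    t0 <- 0; cur <- seg$parent[match(s, seg$segment)]
    while (!is.na(cur)) {
      t0 <- t0 + seg$length[match(cur, seg$segment)]
      cur <- seg$parent[match(cur, seg$segment)]
    }
    start[s] <- t0
  }
  start
}

# embedding-space origin of each segment (endpoint of its parent)
segment_origins <- function(topology) {
  seg <- topology$segments
  origin <- matrix(0, nrow(seg), topology$dims,
                   dimnames = list(seg$segment, NULL))
  resolve <- function(s) {
    p <- seg$parent[match(s, seg$segment)]
    if (is.na(p)) return(rep(0, topology$dims))
    resolve(p) + seg$length[match(p, seg$segment)] *
      seg$direction[[match(p, seg$segment)]]
  }
  for (s in seg$segment) origin[s, ] <- resolve(s)
  origin
}

#' Default Y-shaped neural-crest-style topology
#'
#' A root trunk segment (multipotent progenitors) of pseudotime length 1
#' forking into two equal-length branches (glial and sympathoadrenal), with
#' cell allocation (0.5, 0.25, 0.25). The fork sits at pseudotime 1.
#'
#' @param dims embedding dimensionality (first two dims carry the Y shape,
#'   further dims are zero).
#' @return A `topology_spec`.
#' @export
nc_fork_topology <- function(dims = 2) {
  pad <- function(v) c(v, rep(0, dims - 2))
  topology_spec(tibble::tibble(
    segment = c("NC", "glial", "SA"),
    parent = c(NA, "NC", "NC"),
    length = c(1, 1, 1),
    direction = list(pad(c(1, 0)),
                     pad(c(1, 1) / sqrt(2)),
                     pad(c(1, -1) / sqrt(2))),
    fraction = c(0.5, 0.25, 0.25)
  ))
}

#' Simulate cells along a branching trajectory
#'
#' Places `n_cells` uniformly along segment arc-length according to the
#' topology's allocation fractions and embeds them as backbone position plus
#' isotropic Gaussian noise. Ground truth (exact pseudotime and segment per
#' cell) is recorded for recovery testing.
#'
#' @param topology a [topology_spec()].
#' @param n_cells number of cells (>= number of segments).
#' @param embedding_noise_sd isotropic Gaussian noise sd in embedding units.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with `embedding` (cells x dims matrix) and `truth`
#'   (a `synthetic_truth` carrying the per-cell table and fork pseudotime).
#' @export
simulate_trajectory <- function(topology, n_cells,
                                embedding_noise_sd = 0.05, seed = 1) {
  stopifnot(inherits(topology, "topology_spec"))
  if (embedding_noise_sd < 0) stop_cf("embedding_noise_sd must be >= 0")
  seg <- topology$segments
  if (n_cells < nrow(seg)) stop_cf("n_cells must be >= number of segments")
  set.seed(seed)
  counts <- allocate_counts(n_cells, seg$fraction)
  start_t <- segment_start_times(topology)
  origins <- segment_origins(topology)
  cell_seg <- rep(seg$segment, counts)
  u <- stats::runif(n_cells) * rep(seg$length, counts)
  t_true <- start_t[cell_seg] + u
  backbone <- origins[cell_seg, , drop = FALSE] +
    u * do.call(rbind, seg$direction[match(cell_seg, seg$segment)])
  noise <- matrix(stats::rnorm(n_cells * topology$dims,
                               sd = embedding_noise_sd),
                  n_cells, topology$dims)
  emb <- backbone + noise
  ord <- order(t_true)  # deterministic, pseudotime-sorted cell ids
  ids <- sprintf("cell_%04d", seq_len(n_cells))
  emb <- emb[ord, , drop = FALSE]
  rownames(emb) <- ids
  colnames(emb) <- paste0("dim", seq_len(topology$dims))
  # fork pseudotimes: end of any segment with >= 2 children
  kids <- table(stats::na.omit(seg$parent))
  forks <- names(kids)[kids >= 2]
  fork_time <- if (length(forks)) unname(start_t[forks] +
    seg$length[match(forks, seg$segment)]) else numeric(0)
  truth <- structure(list(
    cells = tibble::tibble(cell = ids, t = t_true[ord],
                           segment = cell_seg[ord]),
    topology = topology,
    fork_time = fork_time
  ), class = "synthetic_truth")
  list(embedding = emb, truth = truth)
}

#' Gene-module specification for the expression simulator
#'
#' @param module module id.
#' @param role one of `"early"`, `"late"`, `"neutral"`, `"noise"`,
#'   `"hub-marker"`, `"type-marker"`.
#' @param branch target branch segment (`NA` for neutral/noise/hub-marker).
#' @param baseline,amplitude mean expression floor and activation height
#'   (expected counts at library-size factor 1); amplitude >= 0.
#' @param t_act activation pseudotime; `steepness` the logistic scale.
#' @param t_repress repression pseudotime on the opposing branch (early
#'   modules); `NA` otherwise.
#' @param n_genes genes in the module.
#' @return one-row tibble; rows are concatenated into a module table.
#' @export
module_spec <- function(module, role, branch = NA_character_, baseline = 100,
                        amplitude = 0, t_act = NA_real_, steepness = 0.05,
                        t_repress = NA_real_, n_genes = 10) {
  role <- match.arg(role, c("early", "late", "neutral", "noise",
                            "hub-marker", "type-marker"))
  if (amplitude < 0) stop_cf("amplitude must be >= 0")
  tibble::tibble(module = module, role = role, branch = branch,
                 baseline = baseline, amplitude = amplitude, t_act = t_act,
                 steepness = steepness, t_repress = t_repress,
                 n_genes = as.integer(n_genes))
}

#' Default module table for the Y fork
#'
#' 20 early + 20 late genes per branch, hub markers peaking around the fork,
#' decaying progenitor markers, terminal type markers, and neutral plus pure
#' noise genes. Early modules activate before the fork (pseudotime 1) and are
#' repressed past the fork on the opposing branch; late modules activate
#' after commitment on their own branch only.
#'
#' @param fork_time fork pseudotime of the matching topology.
#' @return tibble of module specifications.
#' @export
default_fork_modules <- function(fork_time = 1) {
  dplyr::bind_rows(
    module_spec("early_glial", "early", "glial", baseline = 300,
                amplitude = 4000, t_act = fork_time - 0.5, steepness = 0.15,
                t_repress = fork_time, n_genes = 20),
    module_spec("early_SA", "early", "SA", baseline = 300,
                amplitude = 4000, t_act = fork_time - 0.5, steepness = 0.15,
                t_repress = fork_time, n_genes = 20),
    module_spec("late_glial", "late", "glial", baseline = 300,
                amplitude = 4000, t_act = fork_time + 0.4, n_genes = 20),
    module_spec("late_SA", "late", "SA", baseline = 300,
                amplitude = 4000, t_act = fork_time + 0.4, n_genes = 20),
    module_spec("hub_marker", "hub-marker", NA, baseline = 300,
                amplitude = 4000, t_act = fork_time - 0.2,
                t_repress = fork_time + 0.2, n_genes = 10),
    module_spec("marker_NC", "type-marker", "NC", baseline = 300,
                amplitude = 4000, t_act = fork_time - 0.5, n_genes = 10),
    module_spec("marker_glial", "type-marker", "glial", baseline = 300,
                amplitude = 4000, t_act = fork_time + 0.3, n_genes = 10),
    module_spec("marker_SA", "type-marker", "SA", baseline = 300,
                amplitude = 4000, t_act = fork_time + 0.3, n_genes = 10),
    module_spec("neutral", "neutral", NA, baseline = 2000, n_genes = 20),
    module_spec("noise", "noise", NA, baseline = 1000, n_genes = 50)
  )
}

# is segment `s` on the root-to-`target` path?
on_target_path <- function(topology, s, target) {
  cur <- target
  seg <- topology$segments
  while (!is.na(cur)) {
    if (identical(cur, s)) return(TRUE)
    cur <- seg$parent[match(cur, seg$segment)]
  }
  FALSE
}

#' Closed-form expected expression of a simulated gene
#'
#' Mean expression (at library-size factor 1) of a module's genes at
#' pseudotime `t` on segment `segment`. Early modules rise logistically on
#' all pre-fork cells and on the target branch, and decay back toward
#' baseline past the repression pseudotime on the opposing branch; late and
#' terminal type-marker modules activate on the target branch only; the NC
#' type marker decays everywhere past its set point; hub markers carry a
#' logistic-up/logistic-down bump around the fork on all segments.
#'
#' @param spec one row of the module table.
#' @param t pseudotime vector; `segment` matching segment ids.
#' @param topology the `topology_spec` used for the trajectory.
#' @return numeric vector of expected counts.
#' @export
module_mean <- function(spec, t, segment, topology) {
  base <- rep(spec$baseline, length(t))
  if (spec$amplitude == 0) return(base)
  up <- logistic((t - spec$t_act) / spec$steepness)
  if (spec$role == "early") {
    on_path <- unname(vapply(segment, function(s)
      on_target_path(topology, s, spec$branch) ||
        on_target_path(topology, spec$branch, s), logical(1)))
    act <- up
    down <- 1 - logistic((t - spec$t_repress) / spec$steepness)
    act[!on_path] <- (up * down)[!on_path]
    return(base + spec$amplitude * act)
  }
  if (spec$role %in% c("late", "type-marker") && !is.na(spec$branch) &&
      !is.na(topology$segments$parent[
        match(spec$branch, topology$segments$segment)])) {
    on_path <- unname(vapply(segment, function(s)
      on_target_path(topology, s, spec$branch) ||
        on_target_path(topology, spec$branch, s), logical(1)))
    act <- ifelse(on_path, up, 0)
    return(base + spec$amplitude * act)
  }
  if (spec$role == "type-marker") {        # root/progenitor marker: decays
    return(base + spec$amplitude * (1 - up))
  }
  if (spec$role == "hub-marker") {
    bump <- up * (1 - logistic((t - spec$t_repress) / spec$steepness))
    return(base + spec$amplitude * bump)
  }
  base
}

#' Expected-mean matrix for a module table
#'
#' @param truth a `synthetic_truth` from [simulate_trajectory()].
#' @param modules module table ([module_spec()] rows).
#' @return genes x cells matrix of expected counts at library factor 1.
#' @export
expected_expression <- function(truth, modules) {
  genes <- expand_gene_table(modules)
  mu <- matrix(0, nrow(genes), nrow(truth$cells),
               dimnames = list(genes$gene, truth$cells$cell))
  for (m in seq_len(nrow(modules))) {
    spec <- modules[m, ]
    mu_m <- module_mean(spec, truth$cells$t, truth$cells$segment,
                        truth$topology)
    mu[genes$module == spec$module, ] <-
      matrix(mu_m, sum(genes$module == spec$module), length(mu_m),
             byrow = TRUE)
  }
  mu
}

expand_gene_table <- function(modules) {
  dplyr::bind_rows(lapply(seq_len(nrow(modules)), function(m) {
    tibble::tibble(
      gene = sprintf("%s_g%02d", modules$module[m],
                     seq_len(modules$n_genes[m])),
      module = modules$module[m], role = modules$role[m],
      branch = modules$branch[m])
  }))
}

#' Simulate a count matrix over a ground-truth trajectory
#'
#' Draws negative-binomial counts with mean `mu_g(cell) * library factor`,
#' adds ERCC spike-in rows with per-cell spike fractions in a stated range,
#' and optionally injects low-quality cells that violate the default QC
#' filter (tiny libraries with few detected genes, or excessive ERCC
#' fraction).
#'
#' @param truth a `synthetic_truth`.
#' @param modules module table; every gene belongs to exactly one module.
#' @param nb_dispersion negative-binomial size parameter (> 0).
#' @param lib_size_lognormal_params `c(meanlog, sdlog)` of the per-cell
#'   library-size factor (factor = lognormal draw, centred on 1 by default).
#' @param ercc_fraction_range clean-cell ERCC read fraction range in [0,1].
#' @param n_low_quality_cells QC-violating cells to append.
#' @param n_ercc number of ERCC spike-in rows.
#' @param seed integer seed.
#' @return An `expr_matrix` (counts). The truth gains `genes`, `modules`,
#'   `lib_factor` and a `low_quality` flag per cell (updated copy returned
#'   as attribute `truth`; retrieve with `attr(x, "truth")`).
#' @export
simulate_expression <- function(truth, modules, nb_dispersion = 10,
                                lib_size_lognormal_params = c(0, 0.2),
                                ercc_fraction_range = c(0.01, 0.10),
                                n_low_quality_cells = 0, n_ercc = 20,
                                seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (nrow(modules) == 0) stop_cf("modules must be non-empty")
  if (nb_dispersion <= 0) stop_cf("nb_dispersion must be > 0")
  tmax <- max(segment_start_times(truth$topology) +
                truth$topology$segments$length)
  bad_act <- !is.na(modules$t_act) & (modules$t_act < 0 | modules$t_act > tmax)
  if (any(bad_act))
    stop_cf("activation pseudotime outside topology range")
  set.seed(seed)
  genes <- expand_gene_table(modules)
  mu <- expected_expression(truth, modules)
  n <- ncol(mu)
  lib <- stats::rlnorm(n, lib_size_lognormal_params[1],
                       lib_size_lognormal_params[2])
  counts <- matrix(stats::rnbinom(length(mu), size = nb_dispersion,
                                  mu = t(t(mu) * lib)),
                   nrow(mu), n, dimnames = dimnames(mu))
  # ERCC rows: draw a per-cell spike fraction, distribute over fixed props
  frac <- stats::runif(n, ercc_fraction_range[1], ercc_fraction_range[2])
  ercc_ids <- sprintf("ERCC-%05d", seq_len(n_ercc))
  props <- (seq_len(n_ercc))^1.5; props <- props / sum(props)
  ercc_counts <- vapply(seq_len(n), function(i) {
    tot <- round(frac[i] / (1 - frac[i]) * sum(counts[, i]))
    stats::rmultinom(1, tot, props)[, 1]
  }, numeric(n_ercc))
  rownames(ercc_counts) <- ercc_ids
  low_quality <- rep(FALSE, n)
  if (n_low_quality_cells > 0) {
    idx <- sample.int(n, n_low_quality_cells)
    lq_ids <- sprintf("lowq_%03d", seq_len(n_low_quality_cells))
    half <- seq_len(ceiling(n_low_quality_cells / 2))
    lq_counts <- matrix(0L, nrow(counts), n_low_quality_cells,
                        dimnames = list(rownames(counts), lq_ids))
    lq_ercc <- matrix(0L, n_ercc, n_low_quality_cells,
                      dimnames = list(ercc_ids, lq_ids))
    for (j in seq_len(n_low_quality_cells)) {
      src <- mu[, idx[j]]
      if (j %in% half) {
        # tiny library, most genes undetected -> fails transcript+gene bounds
        keep <- stats::runif(length(src)) < 0.2
        lam <- src * keep * 0.02
        lq_counts[, j] <- stats::rnbinom(length(src), size = nb_dispersion,
                                         mu = lam)
        lq_ercc[, j] <- stats::rmultinom(1, 500, props)[, 1]
      } else {
        # normal library but spike-dominated -> fails ERCC fraction bound
        lq_counts[, j] <- stats::rnbinom(length(src), size = nb_dispersion,
                                         mu = src)
        tot <- round(0.35 / 0.65 * sum(lq_counts[, j]))
        lq_ercc[, j] <- stats::rmultinom(1, tot, props)[, 1]
      }
    }
    counts <- cbind(counts, lq_counts)
    ercc_counts <- cbind(ercc_counts, lq_ercc)
    truth$cells <- dplyr::bind_rows(
      truth$cells,
      tibble::tibble(cell = lq_ids, t = NA_real_, segment = NA_character_))
    low_quality <- c(low_quality, rep(TRUE, n_low_quality_cells))
    lib <- c(lib, rep(NA_real_, n_low_quality_cells))
  }
  full <- rbind(counts, ercc_counts)
  storage.mode(full) <- "integer"
  truth$genes <- genes
  truth$modules <- modules
  truth$cells$lib_factor <- lib
  truth$cells$low_quality <- low_quality
  out <- expr_matrix(Matrix::Matrix(full, sparse = TRUE),
                     ercc = c(rep(FALSE, nrow(counts)),
                              rep(TRUE, n_ercc)),
                     layer = "counts")
  attr(out, "truth") <- truth
  out
}

#' Simulate regulon-activity scores over a trajectory
#'
#' Each regulon follows one of `n_clusters` smooth trend templates of
#' pseudotime (round-robin assignment) plus Gaussian noise, clipped to
#' [0, 1]. TF log10 expression is generated proportional to the template so
#' that TF-weighting has signal to work with.
#'
#' @param truth a `synthetic_truth` (clean cells only are used).
#' @param n_regulons,n_clusters counts, `n_clusters <= n_regulons`.
#' @param trend_templates list of functions t -> [0,1]; default builds
#'   `n_clusters` distinct templates over the topology's pseudotime range.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param tf_scale multiplier mapping template value to TF log10 expression.
#' @param seed integer seed.
#' @return A `regulon_activity` object; per-regulon true cluster labels in
#'   `$truth_cluster`.
#' @export
simulate_regulon_activity <- function(truth, n_regulons = 30, n_clusters = 5,
                                      trend_templates = NULL, noise_sd = 0.05,
                                      tf_scale = 2, seed = 1) {
  if (noise_sd < 0) stop_cf("noise_sd must be >= 0")
  if (n_clusters > n_regulons) stop_cf("n_clusters must be <= n_regulons")
  cells <- truth$cells
  if (!is.null(cells$low_quality)) cells <- cells[!cells$low_quality, ]
  t <- cells$t
  tmax <- max(t)
  if (is.null(trend_templates))
    trend_templates <- default_trend_templates(n_clusters, tmax)
  if (length(trend_templates) != n_clusters)
    stop_cf("need one template per cluster")
  set.seed(seed)
  cluster <- rep(seq_len(n_clusters), length.out = n_regulons)
  ids <- sprintf("regulon_%02d", seq_len(n_regulons))
  scores <- matrix(0, n_regulons, length(t),
                   dimnames = list(ids, cells$cell))
  tf_expr <- scores
  for (r in seq_len(n_regulons)) {
    base <- trend_templates[[cluster[r]]](t)
    scores[r, ] <- pmin(pmax(base + stats::rnorm(length(t), sd = noise_sd),
                             0), 1)
    tf_expr[r, ] <- pmax(tf_scale * base +
                           stats::rnorm(length(t), sd = noise_sd), 0)
  }
  regulon_activity(scores,
                   tf_map = stats::setNames(sprintf("TF_%02d",
                                                    seq_len(n_regulons)), ids),
                   tf_expr = tf_expr,
                   truth_cluster = stats::setNames(cluster, ids))
}

#' Default smooth trend templates
#'
#' Builds `n` pairwise-distinct smooth functions of pseudotime into [0,1]:
#' an early-decaying trend, a late-rising trend, Gaussian bumps at
#' staggered positions, and a two-peak trend (progenitor states reactivated
#' before commitment show such twin activity peaks). Shapes are chosen to
#' have low pairwise cosine similarity after z-scoring, so planted clusters
#' are genuinely distinct.
#'
#' @param n number of templates; `tmax` pseudotime range end.
#' @return list of functions.
#' @export
default_trend_templates <- function(n = 5, tmax = 2) {
  pool <- list(
    function(t) 0.05 + 0.9 * (1 - logistic((t - 0.25 * tmax) / (0.08 * tmax))),
    function(t) 0.05 + 0.9 * logistic((t - 0.7 * tmax) / (0.08 * tmax)),
    function(t) 0.10 + 0.8 * exp(-(t - 0.5 * tmax)^2 / (2 * (0.08 * tmax)^2)),
    function(t) 0.10 + 0.8 * exp(-(t - 0.3 * tmax)^2 / (2 * (0.06 * tmax)^2)),
    function(t) pmin(0.10 + 0.75 *
                       (exp(-(t - 0.15 * tmax)^2 / (2 * (0.05 * tmax)^2)) +
                        exp(-(t - 0.85 * tmax)^2 / (2 * (0.05 * tmax)^2))),
                     1),
    function(t) 0.10 + 0.8 * exp(-(t - 0.8 * tmax)^2 / (2 * (0.07 * tmax)^2)),
    function(t) 0.05 + 0.9 * (1 - logistic((t - 0.6 * tmax) / (0.05 * tmax)))
  )
  if (n > length(pool)) stop_cf("at most 7 default templates available")
  pool[seq_len(n)]
}

#' One-call synthetic fork dataset
#'
#' Convenience preset bundling trajectory, expression, regulon activity,
#' QC thresholds scaled to the simulated gene panel, hub ground truth
#' (cells in a pseudotime band around the fork), and marker sets for
#' annotation.
#'
#' @param n_cells clean cells; `n_low_quality_cells` QC violators appended.
#' @param embedding_noise_sd trajectory noise sd.
#' @param hub_marker_tolerance fraction of a type-marker module's amplitude
#'   below which the module counts as "at baseline"; hub cells are those
#'   whose type-marker modules are all at baseline (a pseudotime band
#'   around the fork).
#' @param seed master seed (stage seeds derived deterministically).
#' @param n_regulons,n_regulon_clusters regulon simulation sizes.
#' @return list: `counts` (expr_matrix), `embedding`, `truth`, `modules`,
#'   `thresholds` (a [qc_thresholds()]), `markers` (named gene lists),
#'   `regulons` (a `regulon_activity`).
#' @export
simulate_fork_dataset <- function(n_cells = 1000, embedding_noise_sd = 0.05,
                                  n_low_quality_cells = 30,
                                  hub_marker_tolerance = 0.05,
                                  n_regulons = 30, n_regulon_clusters = 5,
                                  seed = 1) {
  topo <- nc_fork_topology()
  traj <- simulate_trajectory(topo, n_cells, embedding_noise_sd,
                              seed = derive_seed(seed, 1))
  modules <- default_fork_modules(fork_time = traj$truth$fork_time[1])
  counts <- simulate_expression(traj$truth, modules,
                                n_low_quality_cells = n_low_quality_cells,
                                seed = derive_seed(seed, 2))
  truth <- attr(counts, "truth")
  # hub = cells whose type-marker modules all sit at baseline (a pseudotime
  # band around the fork, by construction of the marker kinetics)
  marker_mods <- modules[modules$role == "type-marker", ]
  silent <- vapply(seq_len(nrow(marker_mods)), function(m) {
    spec <- marker_mods[m, ]
    mu <- module_mean(spec, truth$cells$t, truth$cells$segment,
                      truth$topology)
    mu <= spec$baseline + hub_marker_tolerance * spec$amplitude
  }, logical(nrow(truth$cells)))
  truth$cells$hub <- !truth$cells$low_quality & rowSums(!silent) == 0
  hub_t <- truth$cells$t[which(truth$cells$hub)]
  truth$hub_band <- if (length(hub_t)) range(hub_t) else c(NA_real_, NA_real_)
  regulons <- simulate_regulon_activity(truth, n_regulons = n_regulons,
                                        n_clusters = n_regulon_clusters,
                                        seed = derive_seed(seed, 3))
  genes <- truth$genes
  markers <- list(
    NC = genes$gene[genes$module == "marker_NC"],
    glial = genes$gene[genes$module == "marker_glial"],
    SA = genes$gene[genes$module == "marker_SA"]
  )
  thresholds <- qc_thresholds(min_transcripts = 5e4, max_transcripts = 6e6,
                              min_genes = 100, max_genes = 1e4,
                              max_ercc_fraction = 0.15)
  list(counts = counts, embedding = traj$embedding, truth = truth,
       modules = modules, thresholds = thresholds, markers = markers,
       regulons = regulons)
}
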