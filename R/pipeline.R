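#' End-to-end trajectory analysis pipeline
#'
#' Runs the full desk-scale workflow on a dataset directory (or the shipped
#' synthetic preset): QC filtering, normalisation, principal-tree fitting
#' on the embedding, pseudotime, fork extraction, association and
#' bifurcation testing, module correlations, regulon weighting/clustering
#' (when regulon activity is present — skipped and recorded otherwise),
#' kNN imputation, annotation and hub detection. Writes every stage result
#' as TSV under `out_dir` plus a `manifest.json` recording parameters, the
#' seed, package version and per-file md5 checksums; reruns with the same
#' config are bit-identical.
#'
#' @param config list of options. Recognised keys: `input` (dataset dir;
#'   `NULL` simulates the default preset), `n_cells`, `n_nodes`, `sigma`,
#'   `lambda`, `spline_df`, `fdr_threshold`, `a_cut`, `fdr_cut`,
#'   `effect_cutoff`, `rate_threshold`, `n_bins`, `window_size`,
#'   `knn_k` (imputation graph), `hub_k` and `resolution` (community graph
#'   and resolution of the hub stage: hub calling needs fine-grained
#'   communities of tens of cells each for the unassigned-fraction rule to
#'   act at per-state granularity),
#'   `marker_threshold`, `hub_cutoff`, `thresholds` (a [qc_thresholds()]
#'   for external datasets; the synthetic preset carries its own). Unknown
#'   keys are rejected.
#' @param out_dir output directory.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of stage results, invisibly; outputs and manifest on disk.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1) {
  defaults <- list(input = NULL, n_cells = 1000, n_nodes = 30, sigma = NULL,
                   lambda = 1, spline_df = 5, fdr_threshold = 1e-4,
                   a_cut = 0.025, fdr_cut = 0.1, effect_cutoff = 0.2,
                   rate_threshold = 0.1, n_bins = 10, window_size = NULL,
                   knn_k = 15, hub_k = 10, resolution = 8,
                   marker_threshold = 0.45,
                   hub_cutoff = 0.8, thresholds = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_cf(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "crestflow",
                   version = as.character(utils::packageVersion("crestflow")),
                   seed = seed, config = cfg, stages = list())
  written <- character(0)
  emit <- function(name, tb) {
    f <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(tb, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, f)
  }
  stage <- function(name, skipped = FALSE) {
    manifest$stages[[name]] <<- list(skipped = skipped)
  }

  # --- input ---------------------------------------------------------------
  if (is.null(cfg$input)) {
    ds <- simulate_fork_dataset(n_cells = cfg$n_cells, seed = seed)
    thresholds <- cfg$thresholds %||% ds$thresholds
    stage("simulate")
  } else {
    ds <- load_dataset(cfg$input)
    thresholds <- cfg$thresholds %||% qc_thresholds()
    stage("load")
  }

  # --- qc + normalisation --------------------------------------------------
  qc <- filter_cells(ds$counts, thresholds)
  emit("qc_report", qc$report)
  stage("qc")
  kept <- subset_expr(ds$counts, cells = qc$kept)
  logm <- normalize_log(kept)
  emb <- ds$embedding[intersect(rownames(ds$embedding), qc$kept), ,
                      drop = FALSE]
  stage("normalize")

  # --- tree + pseudotime ---------------------------------------------------
  tree <- fit_principal_tree(emb, n_nodes = cfg$n_nodes, sigma = cfg$sigma,
                             lambda = cfg$lambda,
                             seed = derive_seed(seed, 11))
  # root = tip with the greatest mean progenitor-marker expression when
  # truth is absent we fall back to the tip minimising embedding norm
  root <- select_root(tree, -rowSums(emb^2))
  pt <- compute_pseudotime(tree, root)
  emit("pseudotime", pt$cells)
  ms <- identify_milestones(tree, pt)
  emit("milestones", ms$milestones)
  stage("tree")

  # --- association ---------------------------------------------------------
  logv <- subset_expr(logm, genes = !logm$ercc)
  assoc <- test_association(logv, pt, spline_df = cfg$spline_df,
                            fdr_threshold = cfg$fdr_threshold,
                            a_cut = cfg$a_cut)
  emit("association", assoc)
  stage("association")

  # --- fork analysis -------------------------------------------------------
  tips <- ms$milestones$node[ms$milestones$kind == "tip" &
                               ms$milestones$node != root]
  fork_res <- NULL
  if (length(tips) >= 2) {
    tips2 <- tips[order(-ms$milestones$t[match(tips, ms$milestones$node)])]
    fp <- extract_path(tree, pt, root, tips2[1:2])
    fork_res <- analyze_fork(logv, fp, spline_df = cfg$spline_df,
                             fdr_cut = cfg$fdr_cut,
                             effect_cutoff = cfg$effect_cutoff,
                             n_bins = cfg$n_bins,
                             rate_threshold = cfg$rate_threshold)
    emit("fork", fork_res)
    stage("fork")
    # module correlations over the two early candidate sets
    b1 <- fork_res$feature[!is.na(fork_res$branch) &
                             fork_res$branch == "branch-1"]
    b2 <- fork_res$feature[!is.na(fork_res$branch) &
                             fork_res$branch == "branch-2"]
    if (length(b1) >= 2 && length(b2) >= 2) {
      wp <- default_window_params(nrow(fp$cells))
      ws <- make_windows(fp, cfg$window_size %||% wp$window_size,
                         wp$step)
      wc <- window_module_correlations(logv, ws,
                                       gene_module("branch1", b1),
                                       gene_module("branch2", b2))
      emit("module_correlations", wc)
      stage("module_correlations")
    } else stage("module_correlations", skipped = TRUE)
  } else {
    stage("fork", skipped = TRUE)
    stage("module_correlations", skipped = TRUE)
  }

  # --- regulons ------------------------------------------------------------
  if (!is.null(ds$regulons)) {
    reg <- ds$regulons
    reg$scores <- reg$scores[, intersect(colnames(reg$scores), qc$kept),
                             drop = FALSE]
    if (!is.null(reg$tf_expr))
      reg$tf_expr <- reg$tf_expr[, colnames(reg$scores), drop = FALSE]
    regw <- if (!is.null(reg$tf_expr)) weight_auc_by_tf(reg) else reg
    ra <- test_association(regw$scores, pt, spline_df = cfg$spline_df,
                           fdr_threshold = cfg$fdr_threshold, a_cut = 0.02)
    keep_reg <- ra$feature[ra$significant]
    if (length(keep_reg) >= 2) {
      tr <- fit_trends(regw$scores[keep_reg, , drop = FALSE], pt,
                       spline_df = cfg$spline_df)
      mc <- cluster_metaregulons(tr, seed = derive_seed(seed, 13))
      emit("metaregulons", mc$clusters)
      bins <- bin_summaries(regw$scores, pt, n_bins = 20)
      emit("regulon_bins", bins)
      stage("regulons")
    } else stage("regulons", skipped = TRUE)
  } else stage("regulons", skipped = TRUE)

  # --- annotation + hub ----------------------------------------------------
  if (!is.null(ds$markers)) {
    adj <- build_knn_graph(emb, k = cfg$knn_k)
    imputed <- knn_smooth(logm, adj, steps = 3)
    ann <- score_cell_types(imputed, ds$markers, cfg$marker_threshold)
    emit("annotation", ann)
    comm <- cluster_cells(emb, k = cfg$hub_k, resolution = cfg$resolution,
                          seed = derive_seed(seed, 17))
    hub <- detect_hub(ann, comm, fraction_cutoff = cfg$hub_cutoff)
    emit("hub_clusters", hub$clusters)
    emit("hub_cells", hub$cells)
    markers_tb <- hub_markers(logv, hub)
    emit("hub_markers", markers_tb)
    stage("annotation")
  } else stage("annotation", skipped = TRUE)

  manifest$checksums <- as.list(tools::md5sum(sort(written)))
  names(manifest$checksums) <- basename(sort(written))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(qc = qc, tree = tree, pseudotime = pt, milestones = ms,
                 association = assoc, fork = fork_res,
                 manifest = manifest))
}
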