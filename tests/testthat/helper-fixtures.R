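# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# default synthetic fork dataset (800 clean cells), cached
fork_dataset <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- simulate_fork_dataset(n_cells = 800, seed = 11)
  .fixtures$ds
}

# fitted tree + pseudotime + fork path on the shared dataset, cached
fork_analysis_inputs <- function() {
  if (!is.null(.fixtures$fa)) return(.fixtures$fa)
  ds <- fork_dataset()
  qc <- filter_cells(ds$counts, ds$thresholds)
  emb <- ds$embedding[intersect(rownames(ds$embedding), qc$kept), ,
                      drop = FALSE]
  logm <- normalize_log(subset_expr(ds$counts, cells = rownames(emb)))
  logv <- subset_expr(logm, genes = !logm$ercc)
  tree <- fit_principal_tree(emb, n_nodes = 30, seed = 21)
  root <- select_root(tree, -rowSums(emb^2))
  pt <- compute_pseudotime(tree, root)
  ms <- identify_milestones(tree, pt)
  tips <- ms$milestones$node[ms$milestones$kind == "tip" &
                               ms$milestones$node != root]
  tips <- tips[order(-ms$milestones$t[match(tips, ms$milestones$node)])]
  fp <- extract_path(tree, pt, root, tips[1:2])
  .fixtures$fa <- list(ds = ds, emb = emb, logm = logm, logv = logv,
                       tree = tree, root = root, pt = pt, ms = ms, fp = fp)
  .fixtures$fa
}

# truth-pseudotime frame of the shared dataset (clean cells)
truth_pt <- function() {
  tt <- fork_dataset()$truth$cells
  tt[!tt$low_quality, c("cell", "t", "segment")]
}

# map estimated branch labels to truth segments by majority vote
branch_to_segment <- function(fp, truth_cells) {
  post <- fp$cells[fp$cells$branch %in% c("branch-1", "branch-2"), ]
  seg <- truth_cells$segment[match(post$cell, truth_cells$cell)]
  vapply(split(seg, post$branch),
         function(s) names(which.max(table(s))), character(1))
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
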