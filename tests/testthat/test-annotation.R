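toy_imputed <- function() {
  # 6 cells, two types with 2 markers each
  m <- rbind(
    a1 = c(10, 10, 0, 0, 9, 0),
    a2 = c(8, 9, 0, 0, 8, 0),
    b1 = c(0, 0, 7, 8, 7, 0),
    b2 = c(0, 0, 9, 7, 8, 0))
  colnames(m) <- paste0("c", 1:6)
  m
}

test_that("cell-type scoring labels unique passers and discards multi-type", {
  m <- toy_imputed()
  markers <- list(A = c("a1", "a2"), B = c("b1", "b2"))
  ann <- score_cell_types(m, markers, thresholds = 0.5)
  expect_equal(ann$label[1:2], c("A", "A"))
  expect_equal(ann$label[3:4], c("B", "B"))
  # c5 exceeds both thresholds -> multi-type, discarded
  expect_equal(ann$label[5], "unassigned")
  expect_equal(ann$reason[5], "multi-type")
  # c6 passes nothing
  expect_equal(ann$reason[6], "no-type")
  # unreachable thresholds unassign everyone with reason no-type
  ann2 <- score_cell_types(m, markers, thresholds = 1.01)
  expect_true(all(ann2$label == "unassigned"))
  expect_true(all(ann2$reason == "no-type"))
  # missing markers are dropped with a warning; empty sets error
  expect_warning(score_cell_types(m, list(A = c("a1", "zz")), 0.5),
                 "absent")
  expect_error(score_cell_types(m, list(A = character(0)), 0.5),
               "non-empty")
})

test_that("raising a threshold never decreases the no-type count", {
  # with the multi-type discard rule, total unassigned need not be
  # monotone (a two-type cell can become singly assigned when one
  # threshold rises); cells passing no score are monotone by construction
  ds <- fork_dataset()
  tt <- ds$truth$cells
  keep <- tt$cell[!tt$low_quality]
  logm <- normalize_log(subset_expr(ds$counts, cells = keep))
  prev <- -1
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    ann <- score_cell_types(logm, ds$markers, thr)
    n_no <- sum(ann$reason == "no-type")
    expect_gte(n_no, prev)
    prev <- n_no
  }
  # and with a single marker set (no multi-type possible), total
  # unassigned is monotone as stated
  prev <- -1
  for (thr in c(0.2, 0.4, 0.6, 0.8)) {
    ann1 <- score_cell_types(logm, ds$markers["glial"], thr)
    n_un <- sum(ann1$label == "unassigned")
    expect_gte(n_un, prev)
    prev <- n_un
  }
})

test_that("hub rule flags clusters at the inclusive 80% cutoff", {
  set.seed(1)
  n_per <- 10
  ann <- tibble::tibble(
    cell = paste0("c", 1:(3 * n_per)),
    label = c(rep(c("T", "unassigned"), c(5, 5)),       # 0.5
              rep(c("T", "unassigned"), c(2, 8)),       # 0.8
              rep(c("T", "unassigned"), c(1, 9))))      # 0.9
  comm <- tibble::tibble(cell = ann$cell, cluster = rep(1:3, each = n_per))
  hub <- detect_hub(ann, comm, fraction_cutoff = 0.8)
  expect_equal(hub$clusters$frac_unassigned, c(0.5, 0.8, 0.9))
  expect_equal(hub$clusters$hub, c(FALSE, TRUE, TRUE))
  expect_equal(sum(hub$cells$hub), 2 * n_per)
  # exclusive convention drops the boundary cluster
  hub2 <- detect_hub(ann, comm, fraction_cutoff = 0.8, inclusive = FALSE)
  expect_equal(hub2$clusters$hub, c(FALSE, FALSE, TRUE))
  # no cluster flagged is a valid empty result
  hub3 <- detect_hub(ann, comm, fraction_cutoff = 0.99)
  expect_equal(sum(hub3$cells$hub), 0)
})

test_that("hub markers rank planted marker genes with correct sign", {
  ds <- fork_dataset()
  fa <- fork_analysis_inputs()
  truth <- ds$truth
  hub_mask <- truth$cells$hub[match(colnames(fa$logv$values),
                                    truth$cells$cell)]
  hm <- hub_markers(fa$logv, hub_mask)
  planted <- truth$genes$gene[truth$genes$module == "hub_marker"]
  top10 <- hm$gene[1:10]
  expect_gte(length(intersect(planted, top10)), 8)
  expect_true(all(hm$effect[hm$gene %in% planted] > 0))
  expect_error(hub_markers(fa$logv, rep(FALSE, ncol(fa$logv$values))),
               "3 cells")
})

test_that("wilcoxon marker test is calibrated on null genes", {
  set.seed(2)
  n <- 160
  y <- matrix(rnorm(200 * n), 200, n,
              dimnames = list(paste0("g", 1:200), paste0("c", 1:n)))
  mask <- rep(c(TRUE, FALSE), each = n / 2)
  hm <- hub_markers(y, mask)
  rate <- mean(hm$p < 0.05)
  ci <- qnorm(0.995) * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), ci)
  # an all-tied gene gets p = 1
  y2 <- rbind(y[1:10, ], tied = rep(1, n))
  hm2 <- hub_markers(y2, mask)
  expect_equal(hm2$p[hm2$gene == "tied"], 1)
})

test_that("end-to-end hub recovery meets sensitivity and specificity", {
  fa <- fork_analysis_inputs()
  ds <- fa$ds
  adj <- build_knn_graph(fa$emb, k = 15)
  imputed <- knn_smooth(fa$logm, adj, steps = 3)
  ann <- score_cell_types(imputed, ds$markers, 0.45)
  comm <- cluster_cells(fa$emb, k = 10, resolution = 8, seed = 7)
  hub <- detect_hub(ann, comm)
  truth_hub <- ds$truth$cells$hub[match(hub$cells$cell,
                                        ds$truth$cells$cell)]
  sens <- mean(hub$cells$hub[truth_hub])
  false_incl <- mean(hub$cells$hub[!truth_hub])
  expect_gte(sens, 0.9)
  expect_lte(false_incl, 0.1)
})
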