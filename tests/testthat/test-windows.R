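simple_pt <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(cell = sprintf("c%03d", 1:n), t = sort(runif(n, 0, 2)),
                 segment = "s")
}

test_that("window construction matches the stated counts and ordering", {
  pt <- simple_pt(100)
  nonint <- make_windows(pt, 20, scheme = "nonintersecting")
  expect_equal(nrow(nonint), 5)
  expect_equal(sum(nonint$n), 100)
  expect_equal(length(unique(unlist(nonint$cells))), 100)  # partition
  slide <- make_windows(pt, 20, step = 10, scheme = "sliding")
  expect_equal(nrow(slide), 9)   # floor((100 - 20) / 10) + 1
  expect_true(all(slide$n == 20))
  expect_true(all(diff(slide$t_center) >= 0))
  expect_true(all(diff(slide$t_min) >= 0))
  expect_warning(make_windows(pt, 5), "unstable")
  expect_error(make_windows(pt, 200), "exceeds")
  # short final nonintersecting block dropped below half size
  pt2 <- simple_pt(108)
  n2 <- make_windows(pt2, 20, scheme = "nonintersecting")
  expect_equal(nrow(n2), 5)   # final block of 8 < 10 dropped
  pt3 <- simple_pt(111)
  n3 <- make_windows(pt3, 20, scheme = "nonintersecting")
  expect_equal(nrow(n3), 6)   # final block of 11 >= 10 kept
})

test_that("windowed correlations recover exact intra/inter structure", {
  pt <- simple_pt(120, seed = 2)
  set.seed(3)
  base <- rnorm(120)
  y <- rbind(a1 = base + rnorm(120, sd = 1e-6),
             a2 = base + rnorm(120, sd = 1e-6),
             b1 = -base + rnorm(120, sd = 1e-6),
             b2 = -base + rnorm(120, sd = 1e-6))
  colnames(y) <- pt$cell
  ws <- make_windows(pt, 30, 15)
  wc <- window_module_correlations(y, ws, gene_module("A", c("a1", "a2")),
                                   gene_module("B", c("b1", "b2")))
  expect_equal(wc$intra_a, rep(1, nrow(wc)), tolerance = 1e-6)
  expect_equal(wc$intra_b, rep(1, nrow(wc)), tolerance = 1e-6)
  expect_equal(wc$inter, rep(-1, nrow(wc)), tolerance = 1e-6)
  # modules must be disjoint and present
  expect_error(window_module_correlations(
    y, ws, gene_module("A", c("a1", "a2")),
    gene_module("B", c("a1", "b1"))), "disjoint")
  expect_error(window_module_correlations(
    y, ws, gene_module("A", c("a1", "zz")),
    gene_module("B", "b1")), "absent")
})

test_that("independent modules have near-zero inter-module correlation", {
  pt <- simple_pt(400, seed = 4)
  set.seed(5)
  y <- matrix(rnorm(10 * 400), 10, 400,
              dimnames = list(c(paste0("a", 1:5), paste0("b", 1:5)),
                              pt$cell))
  ws <- make_windows(pt, 50, 25)
  wc <- window_module_correlations(y, ws,
                                   gene_module("A", paste0("a", 1:5)),
                                   gene_module("B", paste0("b", 1:5)))
  expect_lt(mean(abs(wc$inter)), 0.15)
})

test_that("intra computed via the inter formula on (A, A) is consistent", {
  # mean over ordered AxA pairs (excluding the diagonal) equals the mean
  # over unordered distinct pairs, by symmetry of the correlation matrix
  pt <- simple_pt(90, seed = 6)
  set.seed(7)
  y <- matrix(rnorm(4 * 90), 4, 90,
              dimnames = list(paste0("a", 1:4), pt$cell))
  ws <- make_windows(pt, 30, 30)
  for (w in seq_len(nrow(ws))) {
    cm <- cor(t(y[, ws$cells[[w]]]))
    intra <- mean(cm[upper.tri(cm)])
    inter_aa <- (sum(cm) - sum(diag(cm))) / (length(cm) - nrow(cm))
    expect_equal(intra, inter_aa, tolerance = 1e-12)
  }
})

test_that("constant genes are excluded from a window's pairs", {
  pt <- simple_pt(60, seed = 8)
  set.seed(9)
  y <- rbind(a1 = rnorm(60), a2 = rnorm(60), a3 = rep(1, 60),
             b1 = rnorm(60))
  colnames(y) <- pt$cell
  ws <- make_windows(pt, 30, 30)
  wc <- window_module_correlations(y, ws,
                                   gene_module("A", c("a1", "a2", "a3")),
                                   gene_module("B", "b1"))
  expect_true(all(wc$n_constant == 1))
  expect_true(all(is.finite(wc$intra_a)))
  # everything constant -> undefined, not zero
  y0 <- rbind(a1 = rep(1, 60), a2 = rep(2, 60), b1 = rep(3, 60))
  colnames(y0) <- pt$cell
  wc0 <- window_module_correlations(y0, ws, gene_module("A", c("a1", "a2")),
                                    gene_module("B", "b1"))
  expect_true(all(is.na(wc0$inter)))
})

test_that("mapping-aggregated correlations degenerate correctly", {
  fa <- fork_analysis_inputs()
  genes <- fa$ds$truth$genes
  mA <- gene_module("eg", genes$gene[genes$module == "early_glial"][1:8])
  mB <- gene_module("es", genes$gene[genes$module == "early_SA"][1:8])
  tips <- fa$ms$milestones$node[fa$ms$milestones$kind == "tip" &
                                  fa$ms$milestones$node != fa$root]
  tips <- tips[order(-fa$ms$milestones$t[match(tips,
                                               fa$ms$milestones$node)])]
  # hard R: no sampling variability, sd identically zero
  hard_tree <- fa$tree
  hard_tree$R <- (fa$tree$R == apply(fa$tree$R, 1, max)) * 1
  hard_tree$R <- hard_tree$R / rowSums(hard_tree$R)
  agg <- correlations_over_mappings(fa$logv, hard_tree, fa$pt, fa$root,
                                    tips[1:2], mA, mB, n_mappings = 3,
                                    window_size = 80, step = 40, seed = 3)
  expect_true(all(agg$sd < 1e-12, na.rm = TRUE))
  # n_mappings = 1 equals the single-mapping result, sd flagged 0
  expect_warning(
    one <- correlations_over_mappings(fa$logv, hard_tree, fa$pt, fa$root,
                                      tips[1:2], mA, mB, n_mappings = 1,
                                      window_size = 80, step = 40, seed = 4),
    "sd")
  expect_true(all(one$sd == 0))
})
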