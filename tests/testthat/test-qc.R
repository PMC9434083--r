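toy_counts <- function() {
  # 6 cells engineered around the default thresholds (gene bounds scaled)
  set.seed(1)
  genes <- 200
  base <- matrix(rpois(genes * 6, 400), genes, 6,
                 dimnames = list(sprintf("g%03d", 1:genes),
                                 paste0("c", 1:6)))
  base[, 2] <- rpois(genes, 10)              # low transcripts
  base[121:200, 3] <- 0                      # few detected genes
  base[, 3][1:120] <- rpois(120, 600)
  ercc <- matrix(rpois(5 * 6, 50), 5, 6,
                 dimnames = list(sprintf("ERCC-%03d", 1:5), paste0("c", 1:6)))
  ercc[, 4] <- 30000                         # spike-dominated cell
  expr_matrix(rbind(base, ercc), layer = "counts")
}

toy_thresholds <- qc_thresholds(min_transcripts = 5e4, max_transcripts = 6e6,
                                min_genes = 150, max_genes = 1e4,
                                max_ercc_fraction = 0.15)

test_that("filter_cells keeps exactly the cells satisfying all thresholds", {
  m <- toy_counts()
  qc <- filter_cells(m, toy_thresholds)
  expect_setequal(qc$kept, c("c1", "c5", "c6"))
  rep <- qc$report
  expect_equal(rep$reason[rep$cell == "c2"], "transcripts")
  expect_equal(rep$reason[rep$cell == "c4"], "ercc_fraction")
  expect_false(rep$kept[rep$cell == "c3"])
  # a cell below the gene bound is excluded for its gene count
  below <- filter_cells(m, qc_thresholds(0, Inf, 1000, 1e4, 1))
  expect_false(below$report$kept[3])
  # vacuous thresholds keep everything
  all_in <- filter_cells(m, qc_thresholds(0, Inf, 0, Inf, 1))
  expect_length(all_in$kept, 6)
  expect_error(filter_cells(normalize_log(m), toy_thresholds),
               class = "crestflow_layer_error")
})

test_that("ERCC fraction rule uses the stated 15% bound", {
  g <- matrix(c(85, 80), 1, 2, dimnames = list("g1", c("a", "b")))
  e <- matrix(c(15, 20), 1, 2, dimnames = list("ERCC-1", c("a", "b")))
  m <- expr_matrix(rbind(g, e))
  qc <- filter_cells(m, qc_thresholds(0, Inf, 0, Inf, 0.15))
  expect_true(qc$report$kept[qc$report$cell == "a"])    # exactly 0.15
  expect_false(qc$report$kept[qc$report$cell == "b"])   # 0.20
})

test_that("normalize_log matches closed forms and preserves structure", {
  m <- expr_matrix(matrix(c(5, 0, 0, 0, 10, 20, 0, 20, 40), 3, 3,
                          dimnames = list(c("g1", "g2", "g3"),
                                          c("a", "b", "c"))))
  out <- normalize_log(m, target_sum = 1e6)
  # single expressed gene scales to the target sum regardless of its count
  expect_equal(out$values["g1", "a"], log10(1 + 1e6))
  # proportional count vectors normalise identically
  expect_equal(out$values[, "b"], out$values[, "c"])
  # all-zero gene stays zero
  expect_true(all(out$values["g3", "a"] == 0))
  # rank order within a cell is preserved
  ds <- fork_dataset()
  logm <- normalize_log(subset_expr(ds$counts, cells = 1:5))
  raw <- as.matrix(ds$counts$values[, 1:5])
  for (j in 1:5)
    expect_equal(rank(raw[, j], ties.method = "average"),
                 rank(as.matrix(logm$values)[, j], ties.method = "average"),
                 ignore_attr = TRUE)
  # zero-total cells are dropped with a warning
  z <- expr_matrix(matrix(c(5, 0), 1, 2,
                          dimnames = list("g1", c("a", "b"))))
  expect_warning(out <- normalize_log(z), "zero-total")
  expect_equal(colnames(out$values), "a")
})

test_that("overdispersion ranking finds planted high-variance genes", {
  set.seed(8)
  n <- 200
  base <- matrix(rnorm(50 * n, mean = 5, sd = 1), 50, n,
                 dimnames = list(sprintf("g%02d", 1:50), NULL))
  base["g01", ] <- rnorm(n, 5, sqrt(10))   # 10x variance, same mean
  base["g02", ] <- 5                       # constant
  colnames(base) <- paste0("c", 1:n)
  m <- expr_matrix(abs(base), layer = "log")
  ranked <- select_overdispersed(m, n_top = 10)
  expect_equal(ranked$gene[1], "g01")
  expect_false("g02" %in% ranked$gene)
  # at most min(n_top, positive residuals) rows, descending residual
  expect_lte(nrow(ranked), 10)
  expect_true(all(diff(ranked$residual) <= 0))
  expect_true(all(ranked$residual > 0))
})

test_that("knn smoothing is the identity at 0 steps, fixes constants, reduces noise, and is linear", {
  set.seed(4)
  n <- 120
  emb <- cbind(runif(n), runif(n))
  rownames(emb) <- paste0("c", 1:n)
  x <- rbind(const = rep(3, n), noise = rnorm(n), a = rnorm(n),
             b = rnorm(n))
  colnames(x) <- rownames(emb)
  m <- expr_matrix(x, ercc = rep(FALSE, 4), layer = "normalized")
  g <- build_knn_graph(emb, k = 15)
  expect_equal(knn_smooth(m, g, steps = 0)$values, x, ignore_attr = TRUE)
  sm <- knn_smooth(m, g, steps = 3)
  expect_equal(unname(sm$values["const", ]), rep(3, n), tolerance = 1e-12)
  expect_lt(var(sm$values["noise", ]), var(x["noise", ]))
  # linearity: smooth(2a + 3b) = 2 smooth(a) + 3 smooth(b)
  comb <- expr_matrix(rbind(z = 2 * x["a", ] + 3 * x["b", ]),
                      ercc = FALSE, layer = "normalized")
  expect_equal(unname(knn_smooth(comb, g, 3)$values["z", ]),
               unname(2 * sm$values["a", ] + 3 * sm$values["b", ]),
               tolerance = 1e-10)
})
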