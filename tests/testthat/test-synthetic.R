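test_that("trajectory simulation places cells on the backbone and respects allocation", {
  topo <- nc_fork_topology()
  # zero noise: every cell sits exactly on its segment's line
  traj <- simulate_trajectory(topo, 300, embedding_noise_sd = 0, seed = 3)
  origins <- crestflow:::segment_origins(topo)
  starts <- crestflow:::segment_start_times(topo)
  cells <- traj$truth$cells
  for (i in seq_len(nrow(cells))) {
    s <- cells$segment[i]
    u <- cells$t[i] - starts[s]
    expected <- origins[s, ] +
      u * topo$segments$direction[[match(s, topo$segments$segment)]]
    expect_equal(unname(traj$embedding[cells$cell[i], ]),
                 unname(expected), tolerance = 1e-12)
  }
  # allocation fractions are honoured exactly
  traj2 <- simulate_trajectory(topo, 400, 0.05, seed = 5)
  counts <- table(traj2$truth$cells$segment)
  expect_equal(unname(counts[c("NC", "glial", "SA")]),
               c(200, 100, 100), ignore_attr = TRUE)
  # determinism
  a <- simulate_trajectory(topo, 100, 0.05, seed = 9)
  b <- simulate_trajectory(topo, 100, 0.05, seed = 9)
  expect_identical(a, b)
})

test_that("topology validation rejects malformed specs", {
  seg <- tibble::tibble(segment = c("a", "b"), parent = c(NA, "a"),
                        length = c(1, 1),
                        direction = list(c(1, 0), c(0, 1)),
                        fraction = c(0.5, 0.5))
  expect_s3_class(topology_spec(seg), "topology_spec")
  bad <- seg; bad$length[2] <- 0
  expect_error(topology_spec(bad), "lengths")
  bad <- seg; bad$direction[[2]] <- c(0, 1, 2)
  expect_error(topology_spec(bad), "inconsistent")
  bad <- seg; bad$parent <- c("b", "a")
  expect_error(topology_spec(bad), "root|tree")
})

test_that("expression means follow the stated logistic model", {
  topo <- nc_fork_topology()
  traj <- simulate_trajectory(topo, 200, 0.05, seed = 7)
  # amplitude 0 -> constant mean everywhere
  flat <- module_spec("flat", "early", "glial", baseline = 50,
                      amplitude = 0, t_act = 0.5, t_repress = 1)
  mu <- module_mean(flat[1, ], traj$truth$cells$t,
                    traj$truth$cells$segment, topo)
  expect_true(all(mu == 50))
  # far before activation the mean is within 1% of baseline
  early <- module_spec("e", "early", "glial", baseline = 100,
                       amplitude = 1000, t_act = 0.8, steepness = 0.05,
                       t_repress = 1)
  mu0 <- module_mean(early[1, ], 0.2, "NC", topo)
  expect_lt(abs(mu0 - 100) / 100, 0.01)
  # late module stays at baseline off its target branch
  late <- module_spec("l", "late", "SA", baseline = 100, amplitude = 1000,
                      t_act = 1.4, steepness = 0.05)
  expect_equal(module_mean(late[1, ], 1.8, "glial", topo), 100)
  expect_gt(module_mean(late[1, ], 1.8, "SA", topo), 1000)
})

test_that("simulated counts match the closed-form mean (Monte Carlo)", {
  # 2000 cells pinned at one pseudotime; empirical mean within 3 SE of mu
  topo <- nc_fork_topology()
  truth <- structure(list(
    cells = tibble::tibble(cell = sprintf("c%04d", 1:2000), t = 0.9,
                           segment = "NC"),
    topology = topo, fork_time = 1), class = "synthetic_truth")
  mod <- module_spec("e", "early", "glial", baseline = 300,
                     amplitude = 4000, t_act = 0.5, steepness = 0.15,
                     t_repress = 1, n_genes = 1)
  cnt <- simulate_expression(truth, mod, nb_dispersion = 10,
                             lib_size_lognormal_params = c(0, 0),
                             n_low_quality_cells = 0, seed = 13)
  mu <- module_mean(mod[1, ], 0.9, "NC", topo)
  x <- as.numeric(cnt$values["e_g01", ])
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - mu), 3 * se)
})

test_that("expression simulation validates configuration", {
  topo <- nc_fork_topology()
  traj <- simulate_trajectory(topo, 50, 0.05, seed = 1)
  bad <- module_spec("x", "late", "SA", amplitude = 10, t_act = 5)
  expect_error(simulate_expression(traj$truth, bad, seed = 1),
               "activation pseudotime")
  expect_error(simulate_expression(traj$truth, bad[0, ], seed = 1),
               "non-empty")
})

test_that("planted genes recover a positive slope along their target path", {
  ds <- fork_dataset()
  truth <- ds$truth
  logm <- normalize_log(subset_expr(
    ds$counts, cells = truth$cells$cell[!truth$cells$low_quality]))
  y <- as.matrix(logm$values)
  genes <- truth$genes[truth$genes$role %in% c("early", "late"), ]
  tt <- truth$cells[!truth$cells$low_quality, ]
  ok <- vapply(seq_len(nrow(genes)), function(i) {
    target <- genes$branch[i]
    path <- tt$cell[tt$segment %in% c("NC", target)]
    stats::coef(stats::lm(y[genes$gene[i], path] ~
                            tt$t[match(path, tt$cell)]))[2] > 0
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("regulon activity simulation honours its contracts", {
  ds <- fork_dataset()
  truth <- ds$truth
  # all scores within [0, 1]
  expect_true(all(ds$regulons$scores >= 0 & ds$regulons$scores <= 1))
  # zero noise: identical templates give within-cluster trend correlation 1
  reg0 <- simulate_regulon_activity(truth, n_regulons = 10, n_clusters = 5,
                                    noise_sd = 0, seed = 3)
  cl <- reg0$truth_cluster
  for (k in unique(cl)) {
    members <- names(cl)[cl == k]
    if (length(members) < 2) next
    cc <- stats::cor(t(reg0$scores[members, , drop = FALSE]))
    expect_equal(min(cc), 1, tolerance = 1e-12)
  }
  # with noise, within-cluster correlation beats between-cluster
  reg <- ds$regulons
  cc <- stats::cor(t(reg$scores))
  same <- outer(reg$truth_cluster, reg$truth_cluster, "==")
  diag(same) <- NA
  expect_gt(mean(cc[same & !is.na(same)]),
            mean(cc[!same & !is.na(same)]))
  expect_error(simulate_regulon_activity(truth, noise_sd = -1),
               "noise_sd")
  expect_error(simulate_regulon_activity(truth, n_regulons = 3,
                                         n_clusters = 5), "n_clusters")
})

test_that("generators are seed-reproducible end to end", {
  a <- simulate_fork_dataset(n_cells = 150, seed = 42)
  b <- simulate_fork_dataset(n_cells = 150, seed = 42)
  expect_identical(as.matrix(a$counts$values), as.matrix(b$counts$values))
  expect_identical(a$embedding, b$embedding)
  expect_identical(a$regulons$scores, b$regulons$scores)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("every injected low-quality cell fails the default filter", {
  ds <- fork_dataset()
  qc <- filter_cells(ds$counts, ds$thresholds)
  lq <- ds$truth$cells$low_quality[match(qc$report$cell,
                                         ds$truth$cells$cell)]
  expect_true(all(!qc$report$kept[lq]))
  expect_true(all(qc$report$kept[!lq]))
})
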