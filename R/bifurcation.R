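#' Test genes for branch-dependent trends at a fork
#'
#' Fits, per gene and over the post-fork cells of the two branches, the
#' model `g ~ s(pseudotime) + s(pseudotime):Branch + Branch` (a shared
#' smooth plus branch-specific smooth deviations and branch intercepts) and
#' compares it against the no-interaction model
#' `g ~ s(pseudotime) + Branch` with an F-test on the interaction columns.
#' P-values are BH-corrected across genes; genes with `q < fdr_cut` are
#' flagged as candidate branch-specific. The test is exactly symmetric
#' under swapping the branch labels.
#'
#' @param features feature x cell matrix or `expr_matrix`.
#' @param fork_path a two-branch `fork_path` from [extract_path()].
#' @param spline_df spline degrees of freedom of the smooth.
#' @param fdr_cut candidate cutoff on the BH q-value (default 0.1).
#' @return A `fork_stats` tibble: feature, statistic, p, q, candidate.
#' @export
test_fork <- function(features, fork_path, spline_df = 5, fdr_cut = 0.1) {
  stopifnot(inherits(fork_path, "fork_path"))
  cells <- fork_path$cells
  if (!all(c("branch-1", "branch-2") %in% cells$branch))
    stop_cf(paste("fork_path has a single branch:",
                  "use test_association for one-path analysis"))
  post <- cells[cells$branch %in% c("branch-1", "branch-2"), ]
  for (b in c("branch-1", "branch-2"))
    if (sum(post$branch == b) < spline_df + 2)
      stop_cf(sprintf("branch %s has too few cells", b))
  y <- feature_matrix(features)[, post$cell, drop = FALSE]
  basis <- splines::ns(post$t, df = spline_df)
  is_b2 <- as.numeric(post$branch == "branch-2")
  # centred branch contrast keeps the design balanced under label swap
  contrast <- is_b2 - 0.5
  x_red <- cbind(1, basis, contrast)
  x_full <- cbind(x_red, basis * contrast)
  yy <- t(y)
  qr_full <- qr(x_full)
  qr_red <- qr(x_red)
  rss_full <- colSums(qr.resid(qr_full, yy)^2)
  rss_red <- colSums(qr.resid(qr_red, yy)^2)
  df1 <- ncol(x_full) - ncol(x_red)
  df2 <- nrow(x_full) - ncol(x_full)
  fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  degenerate <- rss_red < .Machine$double.eps * nrow(yy)
  pval <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  pval[degenerate] <- 1
  qval <- stats::p.adjust(pval, "BH")
  out <- tibble::tibble(feature = rownames(y), statistic = unname(fstat),
                        p = unname(pval), q = unname(qval),
                        candidate = unname(qval < fdr_cut & !degenerate))
  attr(out, "fdr_cut") <- fdr_cut
  attr(out, "spline_df") <- spline_df
  class(out) <- c("fork_stats", class(out))
  out
}

#' Assign candidate genes to the branch they upregulate on
#'
#' For every candidate gene and each branch, fits the linear model
#' `g ~ pseudotime` along the progenitor-to-terminal path (pre-fork cells
#' plus that branch). The gene is assigned to a branch when its slope there
#' is positive with BH fdr below `upreg_fdr` and its mean post-fork
#' expression exceeds the other branch's by at least `effect_cutoff`;
#' genes qualifying on both branches (or neither) stay unassigned.
#'
#' @param fork_stats output of [test_fork()].
#' @param features the matrix used for `fork_stats`.
#' @param fork_path the same two-branch `fork_path`.
#' @param upreg_fdr BH fdr cutoff on the upregulation slope (default 0.05).
#' @param effect_cutoff required post-fork mean-expression margin between
#'   branches, on the scale of `features` (default 0.2, log-scale oriented).
#' @return A `branch_assignment` tibble: feature, branch (`"branch-1"`,
#'   `"branch-2"` or `NA`), per-branch slope, upreg_q and post-fork means.
#' @export
assign_branch_specific <- function(fork_stats, features, fork_path,
                                   upreg_fdr = 0.05, effect_cutoff = 0.2) {
  stopifnot(inherits(fork_path, "fork_path"))
  y <- feature_matrix(features)
  cand <- fork_stats$feature[fork_stats$candidate]
  cells <- fork_path$cells
  res <- purrr::map_dfr(c("branch-1", "branch-2"), function(b) {
    path <- cells[cells$branch %in% c("pre-fork", b), ]
    x <- cbind(1, path$t)
    qr_x <- qr(x)
    yy <- t(y[cand, path$cell, drop = FALSE])
    beta <- qr.coef(qr_x, yy)
    resid <- qr.resid(qr_x, yy)
    sigma2 <- colSums(resid^2) / (nrow(x) - 2)
    se <- sqrt(sigma2 * solve(crossprod(x))[2, 2])
    tval <- beta[2, ] / se
    pval <- 2 * stats::pt(abs(tval), df = nrow(x) - 2, lower.tail = FALSE)
    post <- cells[cells$branch == b, ]
    post_mean <- rowMeans(y[cand, post$cell, drop = FALSE])
    tibble::tibble(feature = cand, branch = b,
                   slope = unname(beta[2, ]), upreg_p = unname(pval),
                   post_mean = unname(post_mean))
  })
  res$upreg_q <- stats::p.adjust(res$upreg_p, "BH")
  wide <- tidyr::pivot_wider(res, id_cols = "feature",
                             names_from = "branch",
                             values_from = c("slope", "upreg_p", "upreg_q",
                                             "post_mean"))
  pass1 <- wide$`slope_branch-1` > 0 & wide$`upreg_q_branch-1` < upreg_fdr &
    (wide$`post_mean_branch-1` - wide$`post_mean_branch-2`) >= effect_cutoff
  pass2 <- wide$`slope_branch-2` > 0 & wide$`upreg_q_branch-2` < upreg_fdr &
    (wide$`post_mean_branch-2` - wide$`post_mean_branch-1`) >= effect_cutoff
  branch <- rep(NA_character_, nrow(wide))
  branch[pass1 & !pass2] <- "branch-1"
  branch[pass2 & !pass1] <- "branch-2"
  n_both <- sum(pass1 & pass2, na.rm = TRUE)
  if (n_both > 0)
    warn(sprintf("%d gene(s) significant on both branches: unassigned",
                 n_both))
  out <- dplyr::bind_cols(tibble::tibble(feature = wide$feature,
                                         branch = branch),
                          wide[, setdiff(names(wide), "feature")])
  attr(out, "upreg_fdr") <- upreg_fdr
  attr(out, "effect_cutoff") <- effect_cutoff
  class(out) <- c("branch_assignment", class(out))
  out
}

#' Relative expression rate over pseudotime bins
#'
#' Given the mean fitted expression `f(b)` per bin, the relative rate at an
#' interior bin is `r(b) = (f(b+1) - f(b-1)) / (max f - min f)`; the first
#' and last bins are `NA`. Always in [-1, 1] when defined.
#'
#' @param f numeric vector of per-bin mean fitted expression.
#' @return numeric vector of rates, same length as `f`.
#' @export
activation_rate <- function(f) {
  n <- length(f)
  rng <- max(f) - min(f)
  r <- rep(NA_real_, n)
  if (n < 3 || rng == 0) return(r)
  r[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / rng
  r
}

# first interior bin whose rate exceeds the threshold (NA if none/degenerate)
activation_call <- function(f, rate_threshold) {
  if (max(f) == min(f))
    return(list(bin = NA_integer_, degenerate = TRUE))
  r <- activation_rate(f)
  hit <- which(!is.na(r) & r > rate_threshold)
  list(bin = if (length(hit)) hit[1] else NA_integer_, degenerate = FALSE)
}

#' Activation timing of genes along a progenitor-to-terminal path
#'
#' Splits the path's pseudotime range into `n_bins` equal-width bins,
#' averages the fitted trend within each bin, computes the relative
#' expression rate per interior bin ([activation_rate()]), and calls the
#' activation at the first bin whose rate exceeds `rate_threshold`. Genes
#' activating at or before the fork pseudotime are labelled `"early"`,
#' after it `"late"`; genes with no qualifying bin (or a flat trend) are
#' `"not-activated"`.
#'
#' @param trend a `fitted_trend` from [path_trend()] (single path).
#' @param fork_time fork pseudotime; defaults to the trend's attribute.
#' @param n_bins number of pseudotime bins (default 10).
#' @param rate_threshold activation threshold on the relative rate
#'   (default 0.1).
#' @return tibble: feature, activation_bin, activation_t (bin centre),
#'   timing in early/late/not-activated, degenerate.
#' @export
activation_timing <- function(trend, fork_time = NULL, n_bins = 10,
                              rate_threshold = 0.1) {
  fork_time <- fork_time %||% attr(trend, "fork_time")
  tb <- tibble::as_tibble(trend)
  purrr::map_dfr(split(tb, tb$feature), function(d) {
    rng <- range(d$grid_t)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    bin <- pmin(findInterval(d$grid_t, breaks, rightmost.closed = TRUE),
                n_bins)
    f <- vapply(split(d$fitted, factor(bin, levels = seq_len(n_bins))),
                mean, numeric(1))
    if (length(d$grid_t) < n_bins)
      warn("trend grid coarser than the bin count")
    call <- activation_call(f, rate_threshold)
    centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
    act_t <- if (is.na(call$bin)) NA_real_ else centers[call$bin]
    timing <- if (is.na(call$bin)) "not-activated"
              else if (!is.null(fork_time) && !is.na(fork_time) &&
                       act_t <= fork_time) "early" else "late"
    tibble::tibble(feature = d$feature[1], activation_bin = call$bin,
                   activation_t = act_t, timing = timing,
                   degenerate = call$degenerate)
  })
}

#' Full bifurcation analysis at a fork
#'
#' Runs [test_fork()], [assign_branch_specific()] and, for each assigned
#' gene, [activation_timing()] along its own progenitor-to-branch path,
#' returning one row per tested gene.
#'
#' @inheritParams test_fork
#' @inheritParams assign_branch_specific
#' @inheritParams activation_timing
#' @param grid_size trend grid points along each path.
#' @return A `fork_result` tibble: feature, statistic, p, q, candidate,
#'   branch, slope, upreg_q, activation_bin, activation_t, timing.
#' @export
analyze_fork <- function(features, fork_path, spline_df = 5, fdr_cut = 0.1,
                         upreg_fdr = 0.05, effect_cutoff = 0.2, n_bins = 10,
                         rate_threshold = 0.1, grid_size = 100) {
  stats <- test_fork(features, fork_path, spline_df, fdr_cut)
  assign <- assign_branch_specific(stats, features, fork_path,
                                   upreg_fdr, effect_cutoff)
  out <- dplyr::left_join(stats,
                          assign[, c("feature", "branch", "slope_branch-1",
                                     "slope_branch-2", "upreg_q_branch-1",
                                     "upreg_q_branch-2")],
                          by = "feature")
  out$activation_bin <- NA_integer_
  out$activation_t <- NA_real_
  out$timing <- NA_character_
  y <- feature_matrix(features)
  for (b in c("branch-1", "branch-2")) {
    genes <- assign$feature[!is.na(assign$branch) & assign$branch == b]
    if (!length(genes)) next
    tr <- path_trend(y[genes, , drop = FALSE], fork_path, b,
                     spline_df = spline_df, grid_size = grid_size)
    tm <- activation_timing(tr, fork_path$fork_time, n_bins, rate_threshold)
    i <- match(tm$feature, out$feature)
    out$activation_bin[i] <- tm$activation_bin
    out$activation_t[i] <- tm$activation_t
    out$timing[i] <- tm$timing
  }
  attr(out, "fork_time") <- fork_path$fork_time
  attr(out, "rate_threshold") <- rate_threshold
  attr(out, "n_bins") <- n_bins
  class(out) <- c("fork_result", class(out))
  out
}
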