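# normalise the different pseudotime carriers to a (cell, t, segment) frame
as_pt_frame <- function(pseudotime) {
  if (inherits(pseudotime, "pseudotime_field")) {
    out <- pseudotime$cells[, c("cell", "t", "segment")]
    out$segment <- as.character(out$segment)
    return(out)
  }
  if (inherits(pseudotime, "fork_path")) {
    out <- pseudotime$cells[, c("cell", "t", "branch")]
    names(out)[3] <- "segment"
    return(out)
  }
  pt <- tibble::as_tibble(pseudotime)
  if (!all(c("cell", "t") %in% names(pt)))
    stop_cf("pseudotime must have columns cell and t")
  if (is.null(pt$segment)) pt$segment <- "1"
  pt[, c("cell", "t", "segment")]
}

feature_matrix <- function(features) {
  m <- if (inherits(features, "expr_matrix")) as.matrix(features$values)
       else as.matrix(features)
  if (is.null(rownames(m)))
    rownames(m) <- paste0("feature_", seq_len(nrow(m)))
  m
}

# per-segment natural cubic spline design (segment-wise intercepts included)
segment_spline_design <- function(pt, spline_df) {
  segs <- split(seq_len(nrow(pt)), pt$segment)
  small <- names(segs)[lengths(segs) < spline_df + 2]
  if (length(small)) {
    warn(sprintf("dropping segment(s) with too few cells: %s",
                 paste(small, collapse = ", ")))
    segs <- segs[!names(segs) %in% small]
  }
  if (!length(segs)) stop_cf("no segment has enough cells to fit splines")
  rows <- unlist(segs, use.names = FALSE)
  blocks <- lapply(names(segs), function(s) {
    t_s <- pt$t[segs[[s]]]
    b <- splines::ns(t_s, df = spline_df)
    cbind(1, b)
  })
  p_seg <- spline_df + 1
  x <- matrix(0, length(rows), p_seg * length(segs))
  off <- 0; at <- 0
  for (b in blocks) {
    x[at + seq_len(nrow(b)), off + seq_len(p_seg)] <- b
    at <- at + nrow(b); off <- off + p_seg
  }
  list(x = x, rows = rows, segments = names(segs))
}

#' Test features for association with the trajectory
#'
#' Models each feature as a segment-wise natural cubic spline of pseudotime
#' (fitted independently per tree segment) and compares it against the
#' global-intercept null with an F-test. P-values are Benjamini-Hochberg
#' corrected across features; a feature is called significant when its
#' adjusted q-value is below `fdr_threshold` and its fitted amplitude
#' `A = max - min` of fitted values exceeds `a_cut`.
#'
#' @param features feature x cell matrix (or `expr_matrix`); rows tested
#'   independently.
#' @param pseudotime a `pseudotime_field`, `fork_path`, or data frame with
#'   columns cell, t and (optionally) segment.
#' @param spline_df spline degrees of freedom per segment (>= 3).
#' @param fdr_threshold significance cutoff on the BH q-value
#'   (default 1e-4).
#' @param a_cut amplitude cutoff on the fitted range (default 0.025, the
#'   regulon-scale setting; use larger values for log-expression data).
#' @return An `assoc_result` tibble: feature, statistic (F), p, q, A,
#'   significant, degenerate.
#' @export
test_association <- function(features, pseudotime, spline_df = 5,
                             fdr_threshold = 1e-4, a_cut = 0.025) {
  if (spline_df < 3) stop_cf("spline_df must be >= 3")
  y <- feature_matrix(features)
  pt <- as_pt_frame(pseudotime)
  y <- y[, pt$cell, drop = FALSE]
  des <- segment_spline_design(pt, spline_df)
  x <- des$x
  yy <- t(y[, des$rows, drop = FALSE])
  n <- nrow(x); p <- ncol(x)
  qr_x <- qr(x)
  res <- qr.resid(qr_x, yy)
  rss1 <- colSums(res^2)
  rss0 <- colSums(scale(yy, scale = FALSE)^2)
  df1 <- p - 1; df2 <- n - p
  fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  pval <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  fitted <- yy - res
  amp <- apply(fitted, 2, function(f) max(f) - min(f))
  degenerate <- rss0 < .Machine$double.eps * n
  pval[degenerate] <- 1
  fstat[degenerate] <- NA_real_
  amp[degenerate] <- 0
  qval <- stats::p.adjust(pval, "BH")
  out <- tibble::tibble(
    feature = rownames(y), statistic = unname(fstat), p = unname(pval),
    q = unname(qval), A = unname(amp),
    significant = unname(qval < fdr_threshold & amp > a_cut & !degenerate),
    degenerate = unname(degenerate))
  attr(out, "spline_df") <- spline_df
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "a_cut") <- a_cut
  attr(out, "n_cells") <- n
  class(out) <- c("assoc_result", class(out))
  out
}

#' Fit smooth per-segment trends over pseudotime
#'
#' Fits a natural cubic spline of pseudotime to each feature within each
#' segment and evaluates it on an equally spaced pseudotime grid of
#' `grid_size` points per segment. Evaluation never extrapolates: the grid
#' spans the observed pseudotime range of the segment.
#'
#' @inheritParams test_association
#' @param grid_size grid points per segment.
#' @return A `fitted_trend` tibble: feature, segment, grid_t, fitted.
#' @export
fit_trends <- function(features, pseudotime, spline_df = 5, grid_size = 50) {
  y <- feature_matrix(features)
  pt <- as_pt_frame(pseudotime)
  y <- y[, pt$cell, drop = FALSE]
  segs <- split(seq_len(nrow(pt)), pt$segment)
  segs <- segs[lengths(segs) >= spline_df + 2]
  out <- purrr::map_dfr(names(segs), function(s) {
    rows <- segs[[s]]
    t_s <- pt$t[rows]
    basis <- splines::ns(t_s, df = spline_df)
    x <- cbind(1, basis)
    qr_x <- qr(x)
    beta <- qr.coef(qr_x, t(y[, rows, drop = FALSE]))
    beta[is.na(beta)] <- 0
    grid <- seq(min(t_s), max(t_s), length.out = grid_size)
    xg <- cbind(1, stats::predict(basis, grid))
    fit <- xg %*% beta
    tibble::tibble(
      feature = rep(rownames(y), each = grid_size),
      segment = s,
      grid_t = rep(grid, times = nrow(y)),
      fitted = as.vector(fit))
  })
  attr(out, "spline_df") <- spline_df
  attr(out, "grid_size") <- grid_size
  class(out) <- c("fitted_trend", class(out))
  out
}

#' Fit a single trend along a progenitor-to-terminal path
#'
#' Pools the pre-fork cells with one branch of a `fork_path` and fits one
#' continuous spline over the whole progenitor-to-terminal pseudotime
#' range — the input expected by [activation_timing()].
#'
#' @param features feature x cell matrix or `expr_matrix`.
#' @param fork_path a two-branch `fork_path` from [extract_path()].
#' @param branch `"branch-1"` or `"branch-2"`.
#' @param spline_df,grid_size as in [fit_trends()].
#' @return A `fitted_trend` tibble with a single segment named after the
#'   branch; attribute `fork_time` carries the fork pseudotime.
#' @export
path_trend <- function(features, fork_path, branch, spline_df = 5,
                       grid_size = 100) {
  stopifnot(inherits(fork_path, "fork_path"))
  branch <- match.arg(branch, c("branch-1", "branch-2"))
  cells <- fork_path$cells[fork_path$cells$branch %in%
                             c("pre-fork", branch), ]
  pt <- tibble::tibble(cell = cells$cell, t = cells$t, segment = branch)
  out <- fit_trends(features, pt, spline_df = spline_df,
                    grid_size = grid_size)
  attr(out, "fork_time") <- fork_path$fork_time
  out
}
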