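# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom rlang abort warn
NULL

stop_cf <- function(msg, class = "crestflow_error") {
  rlang::abort(msg, class = class)
}

# squared euclidean cross-distances between rows of x and rows of y
cross_dist2 <- function(x, y) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  d2
}

# row-wise variance of a (possibly sparse) matrix without densifying per row
row_vars <- function(m) {
  m <- as.matrix(m)
  n <- ncol(m)
  rowSums((m - rowMeans(m))^2) / (n - 1)
}

logistic <- function(x) 1 / (1 + exp(-x))

# largest-remainder allocation of n items to fractions summing to 1
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# derive a stage seed from a master seed, kept inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# adjusted Rand index between two label vectors (small-n closed form)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_i * sum_j / n2
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
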