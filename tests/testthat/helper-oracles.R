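# Independent oracles, deliberately implemented along different routes than
# the package code they check.

# Exact two-sided independence p-value for a 2 x c table by direct
# enumeration of the first row, with multivariate hypergeometric
# probabilities computed from binomial coefficients (choose), not from
# log-gamma margin factorials.
fisher_oracle_2xc <- function(tab, tol = 1e-12) {
  stopifnot(nrow(tab) == 2)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2) return(1)
  cs <- colSums(tab)
  r1 <- sum(tab[1, ])
  N <- sum(tab)
  grid <- expand.grid(lapply(cs, function(m) 0:m))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  prob <- apply(grid, 1, function(a) {
    prod(choose(cs, a)) / choose(N, r1)
  })
  p_obs <- prod(choose(cs, tab[1, ])) / choose(N, r1)
  sum(prob[prob <= p_obs * (1 + tol)])
}

# Closed-form two-sided hypergeometric test for 2 x 2 tables
fisher_oracle_2x2 <- function(tab, tol = 1e-12) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(d[d <= p_obs * (1 + tol)])
}

# Classic Benjamini-Hochberg step-up rejection rule applied to raw p-values
bh_stepup_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# BH adjusted p-values straight from the step-up definition
bh_adjust_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * ps / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# within-cluster sum of squares recomputed from scratch
inertia_oracle <- function(X, labels) {
  sum(vapply(unique(labels), function(g) {
    sub <- X[labels == g, , drop = FALSE]
    ctr <- colMeans(sub)
    sum(sweep(sub, 2, ctr)^2)
  }, numeric(1)))
}

# random 2 x c contingency table with both row sums equal to 4, built by
# randomly clustering 8 items into at most `c_max` labels
random_pair_table <- function(c_max = 3) {
  labels <- sample(seq_len(c_max), 8, replace = TRUE)
  cond <- rep(1:2, each = 4)
  tab <- table(cond, labels)
  unclass(tab)[, colSums(tab) > 0, drop = FALSE]
}
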