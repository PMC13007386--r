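# Independent oracles used to cross-check the package's statistics. These
# deliberately avoid the code paths they validate.

# Average ranks by explicit counting: 1 + #{x_j < x_i} + #{x_j == x_i, j != i}/2.
oracle_avg_rank <- function(x) {
  vapply(seq_along(x), function(i)
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2, numeric(1))
}

# Pearson correlation written out elementwise.
oracle_pearson <- function(a, b) {
  da <- a - mean(a); db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# Spearman via brute-force average ranks.
oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_avg_rank(x), oracle_avg_rank(y))
}

# Partial correlation as the Pearson correlation of rank-regression
# residuals: regress the ranks of x and of y on the ranks of z, correlate
# the residuals.
oracle_partial_spearman <- function(x, y, z) {
  rx <- oracle_avg_rank(x); ry <- oracle_avg_rank(y); rz <- oracle_avg_rank(z)
  res <- function(v) stats::lm.fit(cbind(1, rz), v)$residuals
  oracle_pearson(res(rx), res(ry))
}

# JZS BF10 by quadrature over the effect size itself: the marginal
# likelihood of t under a Cauchy(0, r) prior on delta (noncentral-t
# likelihood) against the central-t null.
oracle_jzs_bf10 <- function(t_stat, n, r = sqrt(2) / 2) {
  nu <- n - 1
  num <- suppressWarnings(stats::integrate(function(d)
    stats::dt(t_stat, nu, ncp = d * sqrt(n)) * stats::dcauchy(d, 0, r),
    -Inf, Inf, rel.tol = 1e-10)$value)
  num / stats::dt(t_stat, nu)
}

# A 6-vector whose average ranks are exactly uncorrelated with those of m,
# found by enumerating permutations of 1..6 (used for the zero-model
# property).
find_rank_orthogonal <- function(m, skip = 0) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  rm_ <- oracle_avg_rank(m)
  found <- 0
  for (p in perms(1:6)) {
    if (abs(oracle_pearson(oracle_avg_rank(p), rm_)) < 1e-12) {
      found <- found + 1
      if (found > skip) return(as.numeric(p))
    }
  }
  stop("no rank-orthogonal permutation found")
}
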