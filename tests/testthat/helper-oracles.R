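# Independent oracles, deliberately written along different code paths
# than the package implementation.

# Dense direct solve of the full node-balance system, including the
# Dirichlet row, assembled from scratch with base R.
dense_flow_oracle <- function(g, p) {
  mmhg <- 133.322
  n <- nrow(g$nodes)
  root <- which(g$nodes$role == "root")
  term <- which(g$nodes$role == "terminal")
  k <- pi * (g$edges$radius * 1e-3)^4 /
    (8 * p$mu * (g$edges$length * 1e-3))
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (e in seq_len(nrow(g$edges))) {
    i <- g$edges$from[e]; j <- g$edges$to[e]
    A[i, i] <- A[i, i] + k[e]; A[j, j] <- A[j, j] + k[e]
    A[i, j] <- A[i, j] - k[e]; A[j, i] <- A[j, i] - k[e]
  }
  for (t in term) {
    A[t, t] <- A[t, t] + p$gamma_a / p$mu
    b[t] <- b[t] + p$gamma_a / p$mu * p$p_cvp * mmhg
  }
  A[root, ] <- 0; A[root, root] <- 1; b[root] <- p$p_map * mmhg
  solve(A, b)
}

# Monotone bisection on log10(gamma_a) for the perfusion target; valid
# because total perfusion is increasing in gamma_a.
bisect_gamma_a <- function(g, p, q_ref, lo = -20, hi = -2, iter = 200) {
  q_at <- function(lg) {
    p$gamma_a <- 10^lg
    solve_pressures(g, p)$q_total_mlmin
  }
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (q_at(mid) < q_ref) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}

# Textbook two-pass Pearson correlation.
pearson_twopass <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
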