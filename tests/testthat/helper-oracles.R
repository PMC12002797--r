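# Independent brute-force oracles used to cross-check the statistics layer.

# Benjamini-Hochberg from the definition: sort, scale by m/i, enforce
# monotonicity from the largest p downward, cap at 1.
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Spearman rho from the rank (Pearson-on-midranks) definition.
spearman_brute_force <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
# (no ties/zeros assumed; feasible for small n).
signed_rank_exact_p <- function(x) {
  n <- length(x)
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs + 1e-12), mean(v_all >= v_obs - 1e-12)))
}

# simple DDM specs reused across density tests
oracle_specs <- function() {
  list(
    ddm_spec(v = 1, a = 1, w = 0.5, ndt = 0.2),
    ddm_spec(v = -1.5, a = 1.2, w = 0.35, ndt = 0.3),
    ddm_spec(v = 0, a = 2, w = 0.6, ndt = 0.1),
    ddm_spec(v = 2.5, a = 0.9, w = 0.7, ndt = 0.25)
  )
}

# numeric integral of the defective wfpt density on one boundary
wfpt_integral <- function(spec, boundary, upper_lim = 60) {
  integrate(function(t) ddm_wfpt_density(t, boundary, spec),
            spec$ndt, upper_lim, rel.tol = 1e-9)$value
}
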