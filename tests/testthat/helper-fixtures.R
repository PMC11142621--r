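# Shared fixtures built in code.

# Small random covariance set: K groups, p variables, n samples each,
# drawn from a sparse ground truth so partial correlations exist.
make_cov_fixture <- function(K = 2, p = 5, n = 200, alpha_tilde = 0.3,
                             seed = 42) {
  truth <- if (K == 2)
    make_null_scenario("equal", p, alpha_tilde, seed = seed)
  else {
    gp <- lapply(seq_len(K), function(k)
      generate_precision(p, alpha_tilde, seed + k))
    list(precisions = lapply(gp, `[[`, "theta0"))
  }
  data <- sample_groups(truth, n, seed = seed)
  list(truth = truth, data = data,
       covs = sample_covariance(data, center = FALSE))
}

# Dense grid-search oracle for the K=2 fused prox: three refinement stages
# on a rectangular grid, vectorized.
prox_oracle_k2 <- function(a, mu, lam, rho) {
  obj <- function(z1, z2)
    mu / 2 * ((z1 - a[1])^2 + (z2 - a[2])^2) +
      lam * (abs(z1) + abs(z2)) + rho * abs(z1 - z2)
  lo <- min(a, 0) - 0.5
  hi <- max(a, 0) + 0.5
  centre <- rep((lo + hi) / 2, 2)
  width <- hi - lo
  for (step in c(width / 80, width / 3200, width / 128000)) {
    g1 <- centre[1] + seq(-40, 40) * step
    g2 <- centre[2] + seq(-40, 40) * step
    M <- outer(g1, g2, obj)
    idx <- arrayInd(which.min(M), dim(M))
    centre <- c(g1[idx[1]], g2[idx[2]])
  }
  centre
}

# Grid oracle for K=3 (coarser; two stages).
prox_oracle_k3 <- function(a, mu, lam, rho) {
  obj <- function(z) {
    mu / 2 * sum((z - a)^2) + lam * sum(abs(z)) +
      rho * (abs(z[1] - z[2]) + abs(z[1] - z[3]) + abs(z[2] - z[3]))
  }
  centre <- rep(mean(a), 3)
  for (step in c(0.2, 0.02, 0.002, 2e-4)) {
    pts <- seq(-12, 12) * step
    best <- centre
    best_val <- obj(centre)
    for (d1 in pts) for (d2 in pts) for (d3 in pts) {
      z <- centre + c(d1, d2, d3)
      v <- obj(z)
      if (v < best_val) { best_val <- v; best <- z }
    }
    centre <- best
  }
  centre
}
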