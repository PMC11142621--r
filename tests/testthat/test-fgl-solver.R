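test_that("sample covariance matches hand computations", {
  # one variable, observations 1 and -1, uncentered: (1 + 1)/2 = 1
  cs <- sample_covariance(list(matrix(c(1, -1), 2, 1)), center = FALSE)
  expect_equal(cs$covariances[[1]], matrix(1, 1, 1))

  # centering removes a constant column
  X <- cbind(rep(3, 4), rnorm(4))
  cs2 <- sample_covariance(list(X), center = TRUE)
  expect_equal(cs2$covariances[[1]][1, ], c(0, 0))

  # two orthogonal unit observations
  cs3 <- sample_covariance(list(rbind(c(1, 0), c(0, 1))), center = FALSE)
  expect_equal(cs3$covariances[[1]], 0.5 * diag(2))
})

test_that("correlation conversion rescales by diagonal roots", {
  cs <- structure(list(covariances = list(matrix(c(4, 2, 2, 4), 2, 2)),
                       group_sizes = 10L, is_correlation = FALSE,
                       scale_roots = NULL, variables = NULL),
                  class = "covariance_set")
  rr <- correlation_from_cov(cs)
  expect_equal(rr$covariances[[1]], matrix(c(1, 0.5, 0.5, 1), 2, 2))
  expect_equal(rr$scale_roots[[1]], c(2, 2))

  # idempotent on a correlation matrix
  rr2 <- correlation_from_cov(rr)
  expect_equal(rr2$covariances[[1]], rr$covariances[[1]])
  expect_equal(rr2$scale_roots[[1]], c(1, 1))

  cs$covariances[[1]][1, 1] <- 0
  expect_error(correlation_from_cov(cs), "degenerate")
})

test_that("fused prox matches closed forms and a dense grid oracle", {
  # no penalty: identity
  expect_equal(fused_prox(c(0.3, -2, 5), 2, 0, 0), c(0.3, -2, 5))
  # K = 1 soft-threshold
  expect_equal(fused_prox(2, 1, 1, 0), 1)
  # full fusion of two opposite values
  expect_equal(fused_prox(c(1, -1), 1, 0, 1), c(0, 0))
  # diagonal entries pass through
  expect_equal(fused_prox(c(1, -1), 1, 5, 5, is_diagonal = TRUE), c(1, -1))

  set.seed(101)
  for (i in 1:200) {
    a <- runif(2, -2, 2)
    mu <- runif(1, 0.5, 2)
    lam <- runif(1, 0, 1)
    rho <- runif(1, 0, 1)
    got <- fused_prox(a, mu, lam, rho)
    want <- prox_oracle_k2(a, mu, lam, rho)
    expect_lt(max(abs(got - want)), 1e-4)
  }
})

test_that("fused prox is exact for three and four groups", {
  set.seed(77)
  for (i in 1:15) {
    a <- runif(3, -1, 1)
    mu <- runif(1, 0.5, 2)
    lam <- runif(1, 0, 0.5)
    rho <- runif(1, 0, 0.5)
    got <- fused_prox(a, mu, lam, rho)
    want <- prox_oracle_k3(a, mu, lam, rho)
    expect_lt(max(abs(got - want)), 1e-3)
  }
  # K = 4: the returned point beats random candidates and perturbations
  obj4 <- function(z, a, mu, lam, rho) {
    pair <- sum(abs(outer(z, z, `-`)[upper.tri(diag(4))]))
    mu / 2 * sum((z - a)^2) + lam * sum(abs(z)) + rho * pair
  }
  for (i in 1:10) {
    a <- runif(4, -2, 2)
    mu <- runif(1, 0.5, 2); lam <- runif(1, 0, 1); rho <- runif(1, 0, 1)
    z <- fused_prox(a, mu, lam, rho)
    f0 <- obj4(z, a, mu, lam, rho)
    for (j in 1:300) {
      cand <- if (j <= 150) runif(4, -2.5, 2.5) else z + rnorm(4, sd = 0.01)
      expect_gte(obj4(cand, a, mu, lam, rho), f0 - 1e-10)
    }
  }
})

test_that("solver recovers known optima", {
  # identity covariances: the unpenalized gradient vanishes at I and the
  # penalty is zero there, so Theta = I for any lambda, rho
  cs <- structure(list(covariances = list(diag(4), diag(4)),
                       group_sizes = c(8L, 8L), is_correlation = FALSE,
                       scale_roots = NULL, variables = NULL),
                  class = "covariance_set")
  fit <- fgl_admm(cs, fgl_penalty(0.3, 0.2),
                  admm_options(tol_primal = 1e-7, tol_dual = 1e-7,
                               max_iter = 3000))
  expect_lt(max(abs(fit$estimates[[1]] - diag(4))), 1e-5)
  expect_lt(max(abs(fit$estimates[[2]] - diag(4))), 1e-5)

  # lambda = rho = 0: the unpenalized MLE is the covariance inverse
  fx <- make_cov_fixture(K = 1, p = 3, n = 100, seed = 7)
  fit0 <- fgl_admm(fx$covs, fgl_penalty(0, 0),
                   admm_options(tol_primal = 1e-9, tol_dual = 1e-9,
                                max_iter = 10000))
  expect_lt(max(abs(fit0$estimates[[1]] - solve(fx$covs$covariances[[1]]))),
            1e-5)
})

test_that("large fusion penalty matches the pooled single-group solve", {
  # equal-diagonal covariances, where the fusion limit is exactly the
  # pooled problem (unfused diagonals then solve identical equations)
  fx <- make_cov_fixture(K = 2, p = 4, n = 300, seed = 12)
  covs <- fx$covs
  R <- lapply(covs$covariances, function(S) {
    w <- sqrt(diag(S)); R <- S / tcrossprod(w); diag(R) <- 1; R
  })
  covs$covariances <- R
  fit <- fgl_admm(covs, fgl_penalty(0.1, 1000),
                  admm_options(tol_primal = 1e-8, tol_dual = 1e-8,
                               max_iter = 20000))
  expect_lt(max(abs(fit$estimates[[1]] - fit$estimates[[2]])), 1e-4)
  pooled <- covs
  pooled$covariances <- list((R[[1]] + R[[2]]) / 2)
  pooled$group_sizes <- sum(covs$group_sizes)
  single <- fgl_admm(pooled, fgl_penalty(0.1, 0),
                     admm_options(tol_primal = 1e-8, tol_dual = 1e-8,
                                  max_iter = 20000))
  expect_lt(max(abs(fit$estimates[[1]] - single$estimates[[1]])), 1e-4)
})

test_that("weighted variant reduces to congruence transforms", {
  # unit variances: weighted fit equals the plain fit
  fx <- make_cov_fixture(K = 2, p = 4, n = 300, seed = 5)
  covs <- fx$covs
  covs$covariances <- lapply(covs$covariances, function(S) {
    w <- sqrt(diag(S)); R <- S / tcrossprod(w); diag(R) <- 1; R
  })
  pen <- fgl_penalty(0.2, 0.1)
  opts <- admm_options(tol_primal = 1e-8, tol_dual = 1e-8, max_iter = 5000)
  plain <- fgl_admm(covs, pen, opts)
  wtd <- weighted_fgl(covs, pen, opts)
  expect_lt(max(abs(plain$estimates[[1]] - wtd$estimates[[1]])), 1e-6)

  # Sigma = 4I: W = 2I, so Theta_w = W^-1 Theta_R W^-1 = 0.25 * Theta_R,
  # and the correlation problem is the identity case: Theta_w = 0.25 I
  cs4 <- covs
  cs4$covariances <- list(4 * diag(4), 4 * diag(4))
  w4 <- weighted_fgl(cs4, fgl_penalty(0.3, 0.2), opts)
  expect_lt(max(abs(w4$estimates[[1]] - 0.25 * diag(4))), 1e-5)
  expect_lt(max(abs(w4$theta_r[[1]] - diag(4))), 1e-5)
})

test_that("objective evaluates the penalized likelihood exactly", {
  covs <- structure(list(covariances = list(diag(3), diag(3)),
                         group_sizes = c(10L, 10L), is_correlation = FALSE,
                         scale_roots = NULL, variables = NULL),
                    class = "covariance_set")
  pen <- fgl_penalty(1, 1)
  # Theta = I, Sigma = I: tr = p, logdet = 0, penalties 0 -> K * p
  expect_equal(fgl_objective(covs, list(diag(3), diag(3)), pen), 6)

  # symmetric off-diagonal perturbation delta on group 1 only:
  # fit term changes by 2*delta*S_12 - log det change; penalties add
  # 2*lambda*delta + 2*rho*delta
  delta <- 0.1
  Th1 <- diag(3); Th1[1, 2] <- Th1[2, 1] <- delta
  got <- fgl_objective(covs, list(Th1, diag(3)), pen)
  want <- 3 - log(1 - delta^2) + 2 * 1 * delta + 2 * 1 * delta + 3
  expect_equal(got, want)
  expect_gt(got, 6 + 2 * delta + 2 * delta)

  # doubling lambda strictly increases the objective when off-diagonals
  # are nonzero
  expect_gt(fgl_objective(covs, list(Th1, diag(3)), fgl_penalty(2, 1)), got)

  expect_error(fgl_objective(covs, list(-diag(3), diag(3)), pen),
               "positive definite")
})

test_that("KKT residual certifies optimality and flags non-optimality", {
  # exact stationarity at the unpenalized MLE
  fx <- make_cov_fixture(K = 1, p = 4, n = 100, seed = 3)
  S <- fx$covs$covariances[[1]]
  expect_lt(kkt_residual(fx$covs, list(solve(S)), fgl_penalty(0, 0)), 1e-10)

  # solver output at tight tolerance has a small residual
  set.seed(42)
  for (seed in 1:4) {
    fx2 <- make_cov_fixture(K = 2, p = 8, n = 150, seed = seed)
    fit <- fgl_admm(fx2$covs, fgl_penalty(0.15, 0.1),
                    admm_options(tol_primal = 1e-6, tol_dual = 1e-6,
                                 max_iter = 30000))
    expect_lt(max(kkt_residual(fx2$covs, fit, fit$penalty)), 1e-4)
  }

  # identity against a correlated covariance is far from stationary:
  # gap = |0.9| - lambda
  cs <- structure(list(covariances = list(matrix(c(1, 0.9, 0.9, 1), 2, 2)),
                       group_sizes = 10L, is_correlation = FALSE,
                       scale_roots = NULL, variables = NULL),
                  class = "covariance_set")
  res <- kkt_residual(cs, list(diag(2)), fgl_penalty(0.01, 0))
  expect_equal(res, 0.9 - 0.01)
  expect_gt(res, 0.8)
})

test_that("solution beats feasible comparators and decouples at rho = 0", {
  fx <- make_cov_fixture(K = 2, p = 6, n = 200, seed = 21)
  pen <- fgl_penalty(0.2, 0.1)
  opts <- admm_options(max_iter = 5000)
  fit <- fgl_admm(fx$covs, pen, opts)
  obj_fit <- fgl_objective(fx$covs, fit, pen)
  diag_comp <- lapply(fx$covs$covariances,
                      function(S) diag(1 / diag(S)))
  expect_lte(obj_fit, fgl_objective(fx$covs, diag_comp, pen) + 1e-6)
  expect_lte(obj_fit,
             fgl_objective(fx$covs, list(diag(6), diag(6)), pen) + 1e-6)

  # rho = 0 equals independent single-group solves
  pen0 <- fgl_penalty(0.2, 0)
  opts_t <- admm_options(tol_primal = 1e-8, tol_dual = 1e-8,
                         max_iter = 20000)
  joint <- fgl_admm(fx$covs, pen0, opts_t)
  for (k in 1:2) {
    ck <- fx$covs
    ck$covariances <- fx$covs$covariances[k]
    ck$group_sizes <- fx$covs$group_sizes[k]
    sk <- fgl_admm(ck, pen0, opts_t)
    expect_lt(max(abs(joint$estimates[[k]] - sk$estimates[[1]])), 1e-5)
  }
})

test_that("large lasso penalty yields the diagonal solution", {
  fx <- make_cov_fixture(K = 2, p = 5, n = 100, seed = 9)
  lam <- max(vapply(fx$covs$covariances, function(S) max(abs(S)),
                    numeric(1)))
  fit <- fgl_admm(fx$covs, fgl_penalty(lam, 0.05),
                  admm_options(tol_primal = 1e-8, tol_dual = 1e-8,
                               max_iter = 20000))
  for (k in 1:2) {
    Th <- fit$estimates[[k]]
    off <- Th; diag(off) <- 0
    expect_lt(max(abs(off)), 1e-6)
    expect_lt(max(abs(diag(Th) - 1 / diag(fx$covs$covariances[[k]]))), 1e-6)
    # consensus support is exactly empty off-diagonal
    Z <- fit$consensus[[k]]
    expect_true(all(Z[upper.tri(Z)] == 0))
  }
})

test_that("ADMM objective agrees with a direct optimizer on tiny problems", {
  fx <- make_cov_fixture(K = 2, p = 3, n = 200, seed = 31)
  pen <- fgl_penalty(0.15, 0.1)
  fit <- fgl_admm(fx$covs, pen,
                  admm_options(tol_primal = 1e-8, tol_dual = 1e-8,
                               max_iter = 30000))
  obj_admm <- fgl_objective(fx$covs, fit, pen)
  # parameterize both symmetric matrices by their 6 free entries each and
  # refine from the ADMM solution with Nelder-Mead
  pack <- function(th) c(th[[1]][upper.tri(th[[1]], diag = TRUE)],
                         th[[2]][upper.tri(th[[2]], diag = TRUE)])
  unpack <- function(v) lapply(0:1, function(k) {
    M <- matrix(0, 3, 3)
    M[upper.tri(M, diag = TRUE)] <- v[k * 6 + 1:6]
    M + t(M) - diag(diag(M))
  })
  f <- function(v) {
    th <- unpack(v)
    ok <- all(vapply(th, function(M)
      min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > 1e-8,
      logical(1)))
    if (!ok) return(1e10)
    fgl_objective(fx$covs, th, pen)
  }
  ref <- stats::optim(pack(fit$estimates), f,
                      method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
  expect_lt(obj_admm - ref$value, 1e-6)

  # perturbed starts do not find anything better either
  set.seed(1)
  for (i in 1:3) {
    start <- pack(fit$estimates) + rnorm(12, sd = 0.05)
    r2 <- stats::optim(start, f, method = "Nelder-Mead",
                       control = list(maxit = 20000, reltol = 1e-14))
    expect_gte(r2$value, obj_admm - 1e-6)
  }
})

test_that("estimation error shrinks with sample size", {
  truth <- generate_precision(30, 0.1, seed = 60)
  errs <- sapply(c(200, 1600), function(n) {
    lam <- sqrt(log(30) / n)
    mean(sapply(1:20, function(r) {
      d <- sample_groups(list(precisions = list(truth$theta0)), n,
                         seed = 1000 + r * 17 + n)
      cv <- sample_covariance(d, center = FALSE)
      fit <- fgl_admm(cv, fgl_penalty(lam, 0), admm_options())
      sqrt(sum((fit$estimates[[1]] - truth$theta0)^2))
    }))
  })
  expect_lt(errs[2], errs[1])
})
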