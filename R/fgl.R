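#' Penalty specification for the fused graphical lasso
#'
#' @param lasso Nonnegative sparsity penalty (lambda) on off-diagonal
#'   entries of each precision matrix.
#' @param fusion Nonnegative fusion penalty (rho) on off-diagonal
#'   between-group differences.
#' @param weighted Logical; if `TRUE` the penalty is applied on the
#'   correlation scale (see [weighted_fgl()]).
#' @return An object of class `fgl_penalty`.
#' @export
fgl_penalty <- function(lasso, fusion = 0, weighted = FALSE) {
  if (lasso < 0 || fusion < 0)
    stop("penalty parameters must be nonnegative", call. = FALSE)
  structure(list(lasso = lasso, fusion = fusion, weighted = weighted),
            class = "fgl_penalty")
}

#' ADMM solver options
#'
#' Defaults: step `mu = 1`, `max_iter = 1000`, and residual tolerances
#' `1e-5 * p` (filled in from the problem dimension when left `NULL`).
#'
#' @param step ADMM penalty parameter (mu), positive.
#' @param max_iter Maximum number of iterations.
#' @param tol_primal,tol_dual Positive convergence tolerances on the primal
#'   residual ||Theta - Z||_F and dual residual mu * ||Z - Z_old||_F.
#' @return An object of class `admm_options`.
#' @export
admm_options <- function(step = 1, max_iter = 1000L, tol_primal = NULL,
                         tol_dual = NULL) {
  if (step <= 0 || max_iter < 1)
    stop("`step` and `max_iter` must be positive", call. = FALSE)
  structure(list(step = step, max_iter = as.integer(max_iter),
                 tol_primal = tol_primal, tol_dual = tol_dual),
            class = "admm_options")
}

#' Per-group sample covariance matrices
#'
#' Computes `Sigma_hat[k] = (1/n_k) * sum_i (x_i - m)(x_i - m)^T` where `m`
#' is the column-mean vector when `center = TRUE` and zero otherwise (the
#' zero-mean convention used in the simulations).
#'
#' @param data A `group_dataset` (see [sample_groups()]) or a list of
#'   `n_k x p` observation matrices.
#' @param center Logical; subtract column means before forming the
#'   cross-products.  Default `TRUE` for real data; simulations generate
#'   zero-mean samples and pass `FALSE`.
#' @return An object of class `covariance_set`: list with `covariances`,
#'   `group_sizes`, `is_correlation = FALSE`, `scale_roots = NULL`,
#'   `variables` (column names, if any).
#' @export
sample_covariance <- function(data, center = TRUE) {
  obs <- if (inherits(data, "group_dataset")) data$observations else data
  if (!length(obs)) stop("no groups supplied", call. = FALSE)
  covariances <- lapply(obs, function(X) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (n < 1L) stop("empty group", call. = FALSE)
    if (center) X <- sweep(X, 2L, colMeans(X))
    S <- crossprod(X) / n
    (S + t(S)) / 2
  })
  structure(list(covariances = covariances,
                 group_sizes = vapply(obs, nrow, integer(1)),
                 is_correlation = FALSE, scale_roots = NULL,
                 variables = colnames(obs[[1]])),
            class = "covariance_set")
}

#' Convert covariance matrices to correlation form
#'
#' Returns `R_hat[k] = W^-1 Sigma_hat[k] W^-1` with
#' `W[k] = diag(Sigma_hat[k])^(1/2)`, keeping the scale roots for
#' back-transformation.
#'
#' @param covs A `covariance_set`.
#' @return A `covariance_set` with `is_correlation = TRUE` and `scale_roots`
#'   the list of per-group diagonal standard-deviation vectors.
#' @export
correlation_from_cov <- function(covs) {
  stopifnot(inherits(covs, "covariance_set"))
  roots <- lapply(covs$covariances, function(S) {
    d <- diag(S)
    if (any(d <= 0))
      stop("degenerate input: nonpositive variance on the diagonal",
           call. = FALSE)
    sqrt(d)
  })
  corrs <- Map(function(S, w) {
    R <- S / tcrossprod(w)
    diag(R) <- 1
    (R + t(R)) / 2
  }, covs$covariances, roots)
  structure(list(covariances = corrs, group_sizes = covs$group_sizes,
                 is_correlation = TRUE, scale_roots = roots,
                 variables = covs$variables),
            class = "covariance_set")
}

#' Fused-lasso proximal operator for one entry across groups
#'
#' Exact minimizer over `z` of
#' `sum_k (step/2) (z_k - values_k)^2 + lasso * sum_k |z_k|
#'  + fusion * sum_{k<k'} |z_k - z_k'|`
#' (penalties dropped for diagonal entries).  The pairwise-fusion part is
#' solved exactly for any K by isotonic regression of the shifted sorted
#' values; soft-thresholding then applies the l1 part.
#'
#' @param values Numeric vector of length K (one entry per group).
#' @param step Positive quadratic weight (the ADMM step mu).
#' @param lasso,fusion Nonnegative penalty levels (already scaled by the
#'   caller; the solver passes lambda and rho directly).
#' @param is_diagonal Logical; diagonal entries pass through unpenalized.
#' @return Numeric vector of length K.
#' @export
fused_prox <- function(values, step = 1, lasso = 0, fusion = 0,
                       is_diagonal = FALSE) {
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (lasso < 0 || fusion < 0)
    stop("penalties must be nonnegative", call. = FALSE)
  as.numeric(fused_prox_cpp(as.numeric(values), step, lasso, fusion,
                            isTRUE(is_diagonal)))
}

default_tol <- function(opts, p) {
  tp <- if (is.null(opts$tol_primal)) 1e-5 * p else opts$tol_primal
  td <- if (is.null(opts$tol_dual)) 1e-5 * p else opts$tol_dual
  c(tp, td)
}

#' Fused graphical lasso via ADMM
#'
#' Jointly estimates K precision matrices by minimizing the penalized
#' negative Gaussian log-likelihood
#' `sum_k tr(S_k Theta_k) - logdet(Theta_k)` plus an l1 penalty `lasso` on
#' each matrix's off-diagonal entries and a fusion penalty `fusion` on
#' off-diagonal between-group differences.  The Theta-update uses the
#' eigenvalue closed form (every iterate is symmetric positive definite);
#' the consensus Z-update is the exact entrywise fused-lasso prox, so zeros
#' in the reported support are exact.
#'
#' @param covs A `covariance_set`.
#' @param penalty An `fgl_penalty` (the `weighted` flag is ignored here; use
#'   [weighted_fgl()]).
#' @param opts An `admm_options`.
#' @param init Optional warm start: a `precision_set` from a previous fit on
#'   the same problem, whose consensus and dual variables seed the solver.
#' @return An object of class `precision_set`: list with `estimates`
#'   (K symmetric PD matrices), `consensus` (the exactly sparse Z matrices
#'   defining the support), `duals`, `variant`, `converged`, `iterations`,
#'   `primal_residual`, `dual_residual`, `penalty`, `group_sizes`.
#' @export
fgl_admm <- function(covs, penalty, opts = admm_options(), init = NULL) {
  stopifnot(inherits(covs, "covariance_set"),
            inherits(penalty, "fgl_penalty"))
  K <- length(covs$covariances)
  p <- nrow(covs$covariances[[1]])
  S <- array(0, c(p, p, K))
  for (k in seq_len(K)) S[, , k] <- covs$covariances[[k]]
  tol <- default_tol(opts, p)
  if (is.null(init)) {
    Z0 <- array(0, c(p, p, K))
    for (k in seq_len(K)) diag(Z0[, , k]) <- 1 / pmax(diag(S[, , k]), 1e-12)
    U0 <- array(0, c(p, p, K))
  } else {
    Z0 <- simplify2array(init$consensus)
    U0 <- simplify2array(init$duals)
  }
  fit <- admm_fgl_cpp(S, penalty$lasso, penalty$fusion, opts$step,
                      opts$max_iter, tol[1], tol[2], Z0, U0)
  if (!fit$converged)
    warning(sprintf(
      "ADMM did not converge in %d iterations (primal %.3g, dual %.3g)",
      opts$max_iter, fit$primal_residual, fit$dual_residual), call. = FALSE)
  estimates <- lapply(seq_len(K), function(k) {
    Th <- fit$theta[, , k]
    (Th + t(Th)) / 2
  })
  structure(list(estimates = estimates,
                 consensus = lapply(seq_len(K), function(k) fit$z[, , k]),
                 duals = lapply(seq_len(K), function(k) fit$u[, , k]),
                 variant = "plain", converged = fit$converged,
                 iterations = fit$iterations,
                 primal_residual = fit$primal_residual,
                 dual_residual = fit$dual_residual,
                 penalty = penalty, group_sizes = covs$group_sizes),
            class = "precision_set")
}

#' Weighted (correlation-scale) fused graphical lasso
#'
#' Solves the fused graphical lasso on the sample correlation matrices
#' `R_hat[k]` to obtain `Theta_R[k]`, then back-transforms to the
#' covariance scale via `Theta_w[k] = W^-1 Theta_R[k] W^-1` with
#' `W[k] = diag(Sigma_hat[k])^(1/2)`.  This is equivalent to penalizing the
#' precision entries on the correlation scale, which removes the influence
#' of per-variable scaling on the penalty.
#'
#' @inheritParams fgl_admm
#' @return A `precision_set` with `variant = "weighted"`, `estimates` the
#'   back-transformed `Theta_w[k]`, and the correlation-scale fit retained
#'   in `theta_r` and `scale_roots`.
#' @export
weighted_fgl <- function(covs, penalty, opts = admm_options(), init = NULL) {
  corrs <- if (covs$is_correlation) covs else correlation_from_cov(covs)
  fit <- fgl_admm(corrs, penalty, opts, init = init)
  roots <- if (covs$is_correlation)
    lapply(covs$covariances, function(S) rep(1, nrow(S)))
  else corrs$scale_roots
  fit$theta_r <- fit$estimates
  fit$scale_roots <- roots
  fit$estimates <- Map(function(Th, w) Th / tcrossprod(w),
                       fit$theta_r, roots)
  fit$consensus <- Map(function(Z, w) Z / tcrossprod(w),
                       fit$consensus, roots)
  fit$variant <- "weighted"
  fit
}

as_theta_list <- function(thetas) {
  if (inherits(thetas, "precision_set")) thetas$estimates
  else if (is.matrix(thetas)) list(thetas)
  else thetas
}

#' Penalized negative log-likelihood objective
#'
#' Evaluates `sum_k { tr(S_k Theta_k) - logdet(Theta_k) }` plus the
#' off-diagonal lasso and fusion penalties, exactly as minimized by
#' [fgl_admm()].
#'
#' @param covs A `covariance_set`.
#' @param thetas A `precision_set` or list of symmetric PD matrices.
#' @param penalty An `fgl_penalty`.
#' @return The objective value (a scalar).
#' @export
fgl_objective <- function(covs, thetas, penalty) {
  th <- as_theta_list(thetas)
  K <- length(th)
  val <- 0
  for (k in seq_len(K)) {
    ch <- tryCatch(chol(th[[k]]), error = function(e) NULL)
    if (is.null(ch))
      stop("theta matrices must be positive definite", call. = FALSE)
    val <- val + sum(covs$covariances[[k]] * th[[k]]) -
      2 * sum(log(diag(ch)))
    off <- th[[k]]; diag(off) <- 0
    val <- val + penalty$lasso * sum(abs(off))
  }
  if (K > 1 && penalty$fusion > 0) {
    for (k in seq_len(K - 1)) for (kk in (k + 1):K) {
      d <- th[[k]] - th[[kk]]; diag(d) <- 0
      val <- val + penalty$fusion * sum(abs(d))
    }
  }
  val
}

#' KKT stationarity residual
#'
#' Measures optimality of a fitted solution.  For each group the gradient of
#' the smooth part is `G_k = S_k - Theta_k^-1`; stationarity requires
#' `-G_k[i,j]` to lie in the subdifferential interval of the off-diagonal
#' penalty at the solution (a point when the entry or difference is nonzero,
#' a `[-lambda, lambda]` / `[-rho, rho]` interval at zero).  Zero/sign
#' patterns are read from the exactly sparse consensus when available.
#' The diagonal is unpenalized, so its violation is `|G_k[i,i]|`.
#'
#' @inheritParams fgl_objective
#' @return Numeric vector of per-group maximum subgradient violations.
#' @export
kkt_residual <- function(covs, thetas, penalty) {
  th <- as_theta_list(thetas)
  Zs <- if (inherits(thetas, "precision_set")) thetas$consensus else th
  K <- length(th)
  lam <- penalty$lasso; rho <- penalty$fusion
  vapply(seq_len(K), function(k) {
    G <- covs$covariances[[k]] - chol2inv(chol(th[[k]]))
    Zk <- Zs[[k]]
    nz <- Zk != 0
    lo <- ifelse(nz, lam * sign(Zk), -lam)
    hi <- ifelse(nz, lam * sign(Zk), lam)
    if (K > 1 && rho > 0) {
      for (kk in seq_len(K)[-k]) {
        D <- Zk - Zs[[kk]]
        dz <- D != 0
        lo <- lo + ifelse(dz, rho * sign(D), -rho)
        hi <- hi + ifelse(dz, rho * sign(D), rho)
      }
    }
    target <- -G
    viol <- pmax(lo - target, target - hi, 0)
    diag(viol) <- abs(diag(G))
    max(viol)
  }, numeric(1))
}

#' @export
print.precision_set <- function(x, ...) {
  cat(sprintf(
    "precision_set (%s): K = %d, p = %d, lambda = %g, rho = %g\n",
    x$variant, length(x$estimates), nrow(x$estimates[[1]]),
    x$penalty$lasso, x$penalty$fusion))
  cat(sprintf("  %s in %d iterations (primal %.3g, dual %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$primal_residual, x$dual_residual))
  invisible(x)
}
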