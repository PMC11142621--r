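#' Contrast specification for a linear hypothesis on precision entries
#'
#' Encodes the null `a_1 Theta[1]_ij + ... + a_K Theta[K]_ij = 0` tested
#' entrywise, and the significance level used for rejection and confidence
#' intervals.
#'
#' @param coefficients Numeric contrast coefficients `a_1 .. a_K`, not all
#'   zero.  `c(1, -1)` is the two-sample equality test.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(coefficients, alpha = 0.05) {
  if (!length(coefficients) || all(coefficients == 0))
    stop("at least one contrast coefficient must be nonzero", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  structure(list(coefficients = as.numeric(coefficients), alpha = alpha),
            class = "contrast_spec")
}

#' De-biased (de-sparsified) precision estimate
#'
#' One-step bias correction `2 Theta - Theta Sigma Theta`, which removes the
#' first-order penalization bias so entrywise estimates are asymptotically
#' normal.  The result is symmetrized as `(M + t(M)) / 2` to absorb
#' floating-point asymmetry.
#'
#' @param theta Symmetric precision estimate (p x p).
#' @param cov Sample covariance matrix of the same group (p x p).
#' @return The de-biased p x p matrix.
#' @export
debias <- function(theta, cov) {
  if (!all(dim(theta) == dim(cov)))
    stop("`theta` and `cov` dimensions must agree", call. = FALSE)
  M <- 2 * theta - theta %*% cov %*% theta
  (M + t(M)) / 2
}

#' Entrywise asymptotic variance of the contrast statistic
#'
#' `sigma2_ij = sum_k a_k^2 * ( Theta[k]_ii Theta[k]_jj + Theta[k]_ij^2 )`,
#' the plug-in estimator of the limiting variance of
#' `sqrt(n) * (T_ij - true value)`.
#'
#' @param thetas A `precision_set` or list of K precision estimates.
#' @param contrast A `contrast_spec` with K coefficients.
#' @return A symmetric p x p matrix of variance estimates.
#' @export
variance_estimate <- function(thetas, contrast) {
  th <- as_theta_list(thetas)
  a <- contrast$coefficients
  if (length(a) != length(th))
    stop("contrast length must equal the number of groups", call. = FALSE)
  sig2 <- 0
  for (k in seq_along(th)) {
    Th <- th[[k]]
    sig2 <- sig2 + a[k]^2 * (tcrossprod(diag(Th)) + Th^2)
  }
  sig2
}

#' Entrywise de-biased test of a linear contrast of precision matrices
#'
#' Forms `T_ij = sum_k a_k * debias(Theta[k], Sigma[k])_ij`, standard errors
#' `se_ij = sqrt( sum_k a_k^2 (Theta[k]_ii Theta[k]_jj + Theta[k]_ij^2) / n_k )`
#' (which reduces to `sigma_ij / sqrt(n)` for equal group sizes), z-scores,
#' two-sided normal p-values, and confidence intervals
#' `T_ij -/+ z_{1-alpha/2} * se_ij`.  For the weighted variant the de-biasing
#' product still uses the sample covariance (not the correlation), with the
#' weighted estimates `Theta_w` entering both the statistic and the variance
#' plug-in.
#'
#' @param thetas A `precision_set` (plain or weighted).
#' @param covs The `covariance_set` the model was fitted to (covariance
#'   scale; correlation input is refused for de-biasing).
#' @param contrast A `contrast_spec`.
#' @param p_adjust Optional p-value adjustment method passed to
#'   [stats::p.adjust()] over the upper triangle (e.g. `"BH"`); default
#'   `"none"`, matching the raw p-value matrices of the original analyses.
#' @return An object of class `fgl_test_result`: list with symmetric
#'   matrices `statistic`, `stderr`, `zscores`, `pvalues`, `ci_lower`,
#'   `ci_upper`, `reject`, plus `contrast`, `variant`, `group_sizes`,
#'   `debiased` (the per-group de-biased matrices).
#' @export
linear_test <- function(thetas, covs, contrast, p_adjust = "none") {
  stopifnot(inherits(thetas, "precision_set"),
            inherits(covs, "covariance_set"),
            inherits(contrast, "contrast_spec"))
  if (covs$is_correlation)
    stop("de-biasing requires covariance-scale matrices", call. = FALSE)
  th <- thetas$estimates
  K <- length(th)
  a <- contrast$coefficients
  if (length(a) != K)
    stop("contrast length must equal the number of groups", call. = FALSE)
  p <- nrow(th[[1]])
  debiased <- Map(debias, th, covs$covariances)
  stat <- Reduce(`+`, Map(`*`, a, debiased))
  se2 <- 0
  for (k in seq_len(K)) {
    Th <- th[[k]]
    se2 <- se2 + a[k]^2 * (tcrossprod(diag(Th)) + Th^2) /
      covs$group_sizes[k]
  }
  se <- sqrt(se2)
  z <- ifelse(se > 0, stat / se, 0)
  pv <- 2 * pnorm(-abs(z))
  if (!identical(p_adjust, "none")) {
    ut <- upper.tri(pv, diag = TRUE)
    adj <- stats::p.adjust(pv[ut], method = p_adjust)
    pv[ut] <- adj
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  }
  crit <- qnorm(1 - contrast$alpha / 2)
  structure(list(statistic = stat, stderr = se, zscores = z, pvalues = pv,
                 ci_lower = stat - crit * se, ci_upper = stat + crit * se,
                 reject = abs(z) > crit, contrast = contrast,
                 variant = thetas$variant, group_sizes = covs$group_sizes,
                 debiased = debiased),
            class = "fgl_test_result")
}

#' Recompute confidence intervals at another level
#'
#' Updates the `ci_lower`/`ci_upper` (and `reject`) matrices of a test
#' result to `T_ij -/+ z_{1-alpha/2} * se_ij` using the exact normal
#' quantile (1.959964... at alpha = 0.05, the unrounded 97.5% point).
#'
#' @param result An `fgl_test_result`.
#' @param alpha Significance level in (0, 1).
#' @return The updated `fgl_test_result`.
#' @export
confidence_intervals <- function(result, alpha) {
  stopifnot(inherits(result, "fgl_test_result"))
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  crit <- qnorm(1 - alpha / 2)
  result$ci_lower <- result$statistic - crit * result$stderr
  result$ci_upper <- result$statistic + crit * result$stderr
  result$reject <- abs(result$zscores) > crit
  result$contrast$alpha <- alpha
  result
}

#' @export
print.fgl_test_result <- function(x, ...) {
  p <- nrow(x$statistic)
  cat(sprintf(
    "fgl_test_result (%s): p = %d, contrast = (%s), alpha = %g\n",
    x$variant, p, paste(format(x$contrast$coefficients), collapse = ", "),
    x$contrast$alpha))
  ut <- upper.tri(x$pvalues)
  cat(sprintf("  rejected off-diagonal pairs: %d of %d\n",
              sum(x$reject[ut]), sum(ut)))
  invisible(x)
}
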