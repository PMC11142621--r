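#' Tuning grid for (lambda, rho)
#'
#' The default grid is 30 equally spaced points from 0.05 to 0.3 on each
#' axis (step 0.25/29, approximately 0.0086).
#'
#' @param lasso_values Nonnegative lambda candidates.
#' @param fusion_values Nonnegative rho candidates.
#' @return An object of class `tuning_grid`.
#' @export
tuning_grid <- function(lasso_values = seq(0.05, 0.3, length.out = 30),
                        fusion_values = seq(0.05, 0.3, length.out = 30)) {
  if (!length(lasso_values) || !length(fusion_values))
    stop("grid must be nonempty", call. = FALSE)
  if (any(lasso_values < 0) || any(fusion_values < 0))
    stop("grid values must be nonnegative", call. = FALSE)
  structure(list(lasso_values = lasso_values,
                 fusion_values = fusion_values),
            class = "tuning_grid")
}

edge_counts <- function(thetas) {
  Zs <- if (inherits(thetas, "precision_set")) thetas$consensus
        else as_theta_list(thetas)
  vapply(Zs, function(Z) {
    sum(Z[upper.tri(Z)] != 0)
  }, numeric(1))
}

#' Akaike information criterion for a fused graphical lasso fit
#'
#' `AIC = sum_k [ n_k tr(S_k Theta_k) - n_k logdet(Theta_k) + 2 E_k ]` where
#' `E_k` is the number of nonzero upper-triangle off-diagonal entries of
#' group k's estimate, counted on the exactly sparse ADMM consensus.
#'
#' @param covs A `covariance_set` (its `group_sizes` supply the n_k).
#' @param thetas A `precision_set` (or list of PD matrices, in which case
#'   edges are counted on the matrices themselves).
#' @return The AIC value (scalar).
#' @export
fgl_aic <- function(covs, thetas) {
  th <- as_theta_list(thetas)
  E <- edge_counts(thetas)
  val <- 0
  for (k in seq_along(th)) {
    ch <- tryCatch(chol(th[[k]]), error = function(e) NULL)
    if (is.null(ch))
      stop("theta matrices must be positive definite", call. = FALSE)
    n_k <- covs$group_sizes[k]
    val <- val + n_k * sum(covs$covariances[[k]] * th[[k]]) -
      n_k * 2 * sum(log(diag(ch))) + 2 * E[k]
  }
  val
}

#' Select (lambda, rho) by AIC over a grid
#'
#' Fits every grid pair (lambda outer, rho inner, warm-starting along rho)
#' and returns the AIC-minimizing pair.  Ties break to the smallest lambda,
#' then the smallest rho.  Non-converged fits are recorded in the surface
#' but excluded from the argmin.
#'
#' @param covs A `covariance_set`.
#' @param grid A `tuning_grid`.
#' @param opts An `admm_options`.
#' @param weighted Logical; fit the weighted (correlation-scale) variant.
#' @param warm_start Logical; reuse the previous fit along the rho axis.
#' @return List with `lasso` and `fusion` (the selected pair), `fit` (the
#'   winning `precision_set`), and `surface` (a data frame of lambda, rho,
#'   AIC, convergence flag for every grid point).
#' @export
select_tuning <- function(covs, grid = tuning_grid(),
                          opts = admm_options(), weighted = FALSE,
                          warm_start = TRUE) {
  stopifnot(inherits(grid, "tuning_grid"))
  fitter <- if (weighted) weighted_fgl else fgl_admm
  rows <- list()
  best <- NULL
  best_aic <- Inf
  i <- 0L
  for (lam in grid$lasso_values) {
    prev <- NULL
    for (rho in grid$fusion_values) {
      fit <- withCallingHandlers(
        fitter(covs, fgl_penalty(lam, rho), opts,
               init = if (warm_start) prev else NULL),
        warning = function(w) invokeRestart("muffleWarning"))
      prev <- fit
      aic <- if (fit$converged) fgl_aic(covs, fit) else NA_real_
      i <- i + 1L
      rows[[i]] <- data.frame(lasso = lam, fusion = rho, aic = aic,
                              converged = fit$converged)
      if (fit$converged && aic < best_aic) {
        best_aic <- aic
        best <- fit
      }
    }
  }
  surface <- do.call(rbind, rows)
  if (is.null(best))
    stop("no grid point converged; enlarge max_iter or adjust the grid",
         call. = FALSE)
  list(lasso = best$penalty$lasso, fusion = best$penalty$fusion,
       fit = best, surface = surface)
}
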