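#' Configuration for a simulation experiment
#'
#' Bundles the scenario, problem sizes, tuning rule and seed for the
#' coverage and fluctuation experiments.  Defaults mirror the reference
#' study design: p = 100, n = 200 per group, 500 replications, nominal
#' level 0.05.
#'
#' @param scenario One of `"equal"`, `"linear"`, `"three_sample_linear"`.
#' @param p Dimension.
#' @param n Per-group sample size (scalar or one per group).
#' @param alpha_tildes Sparsity parameter(s) of the generator.
#' @param coeffs Scenario coefficients (see [make_null_scenario()]);
#'   defaults: none, 0.5, and c(0.6, 0.9) for the three scenarios.
#' @param replications Number of Monte Carlo replications (>= 1).
#' @param alpha Confidence/significance level.
#' @param tuning Either a list `list(lasso =, fusion =)` of fixed penalties,
#'   a `tuning_grid` for per-replication AIC selection, or `"rate"` for the
#'   theory-rate choice `lasso = fusion = sqrt(log(p) / n)`.
#' @param weighted Logical; use the weighted (correlation-scale) fit.
#' @param redraw_truth Logical; draw a fresh ground truth each replication
#'   (the reference behaviour).  `FALSE` fixes the truth from the master
#'   seed and redraws only the data.
#' @param opts An `admm_options`.
#' @param seed Master integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(scenario = "equal", p = 100, n = 200,
                       alpha_tildes = 0.1, coeffs = NULL,
                       replications = 500, alpha = 0.05,
                       tuning = "rate", weighted = FALSE,
                       redraw_truth = TRUE, opts = admm_options(),
                       seed = 1L) {
  if (replications < 1) stop("`replications` must be >= 1", call. = FALSE)
  if (is.null(coeffs))
    coeffs <- switch(scenario, equal = numeric(), linear = 0.5,
                     three_sample_linear = c(0.6, 0.9))
  if (identical(tuning, "rate"))
    tuning <- list(lasso = sqrt(log(p) / mean(n)),
                   fusion = sqrt(log(p) / mean(n)))
  structure(list(scenario = scenario, p = p, n = n,
                 alpha_tildes = alpha_tildes, coeffs = coeffs,
                 replications = as.integer(replications), alpha = alpha,
                 tuning = tuning, weighted = weighted,
                 redraw_truth = redraw_truth, opts = opts,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One replication: generate/reuse truth, sample, fit, test.  Returns the
# test result, the true contrast matrix, the support, and convergence.
run_one_rep <- function(config, rep_seed, truth = NULL) {
  if (is.null(truth))
    truth <- make_null_scenario(config$scenario, config$p,
                                config$alpha_tildes, config$coeffs,
                                seed = rep_seed)
  data <- sample_groups(truth, config$n, seed = sub_seed(rep_seed, 7L))
  covs <- sample_covariance(data, center = FALSE)
  fit <- if (inherits(config$tuning, "tuning_grid")) {
    sel <- select_tuning(covs, config$tuning, config$opts,
                         weighted = config$weighted)
    sel$fit
  } else {
    pen <- fgl_penalty(config$tuning$lasso, config$tuning$fusion)
    fitter <- if (config$weighted) weighted_fgl else fgl_admm
    withCallingHandlers(fitter(covs, pen, config$opts),
                        warning = function(w) invokeRestart("muffleWarning"))
  }
  contrast <- contrast_spec(truth$contrast, config$alpha)
  res <- linear_test(fit, covs, contrast)
  true_value <- Reduce(`+`, Map(`*`, truth$contrast, truth$precisions))
  list(result = res, true_value = true_value,
       support = truth$contrast_support, converged = fit$converged,
       truth = truth)
}

#' Average-coverage experiment for de-biased confidence intervals
#'
#' Per replication: generate the scenario ground truth, draw group samples,
#' fit the fused graphical lasso (fixed penalties or AIC grid), and record
#' whether each entrywise confidence interval covers the true contrast
#' value.  Coverage is averaged over the support `S` (nonzero entries of
#' the reference combination, diagonal included) and its complement `S^c`.
#' Replications whose fit fails to converge are redrawn from a fresh
#' substream; more than 10% redraws is an error.
#'
#' @param config A `sim_config`.
#' @return An object of class `coverage_report`: list with
#'   `per_entry_coverage` (p x p frequency matrix), `avg_S`, `avg_Sc`,
#'   `avg_all`, `support_used` (the support of the first replication; under
#'   `redraw_truth` membership is tracked per replication), `n_redraws`,
#'   `config`.
#' @export
run_coverage_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$p
  reps <- config$replications
  fixed_truth <- NULL
  if (!config$redraw_truth)
    fixed_truth <- make_null_scenario(config$scenario, p,
                                      config$alpha_tildes, config$coeffs,
                                      seed = config$seed)
  cover_total <- matrix(0, p, p)
  cover_S <- 0; count_S <- 0; cover_Sc <- 0; count_Sc <- 0
  n_redraws <- 0L
  support_first <- NULL
  for (r in seq_len(reps)) {
    attempt <- 0L
    repeat {
      rep_seed <- sub_seed(config$seed, 1000L + r + 100000L * attempt)
      one <- run_one_rep(config, rep_seed, truth = fixed_truth)
      if (one$converged) break
      attempt <- attempt + 1L
      n_redraws <- n_redraws + 1L
      if (n_redraws > 0.1 * reps)
        stop("more than 10% of replications failed to converge",
             call. = FALSE)
    }
    covered <- one$result$ci_lower <= one$true_value &
      one$true_value <= one$result$ci_upper
    cover_total <- cover_total + covered
    S <- one$support
    if (is.null(support_first)) support_first <- S
    cover_S <- cover_S + sum(covered[S])
    count_S <- count_S + sum(S)
    cover_Sc <- cover_Sc + sum(covered[!S])
    count_Sc <- count_Sc + sum(!S)
  }
  structure(list(per_entry_coverage = cover_total / reps,
                 avg_S = cover_S / count_S,
                 avg_Sc = if (count_Sc > 0) cover_Sc / count_Sc else NA_real_,
                 avg_all = (cover_S + cover_Sc) / (count_S + count_Sc),
                 support_used = support_first, n_redraws = n_redraws,
                 config = config),
            class = "coverage_report")
}

#' Fluctuation (normality) experiment for the standardized statistic
#'
#' Collects the replication sample of the standardized contrast statistic
#' `z_ij = T_ij / se_ij` at the requested entries under the configured
#' null, and summarizes each entry's sample with its mean, variance, and a
#' Kolmogorov-Smirnov comparison against N(0, 1).
#'
#' @param config A `sim_config`.
#' @param entries Two-column matrix (or list of length-2 vectors) of (i, j)
#'   index pairs to track.
#' @return List with `samples` (replications x entries matrix of z values),
#'   `summary` (data frame: i, j, mean, var, ks_stat, ks_pvalue),
#'   `n_redraws`, `config`.
#' @export
run_fluctuation_experiment <- function(config, entries) {
  stopifnot(inherits(config, "sim_config"))
  if (is.list(entries)) entries <- do.call(rbind, entries)
  entries <- matrix(as.integer(entries), ncol = 2)
  if (any(entries < 1) || any(entries > config$p))
    stop("entries out of matrix bounds", call. = FALSE)
  reps <- config$replications
  fixed_truth <- NULL
  if (!config$redraw_truth)
    fixed_truth <- make_null_scenario(config$scenario, config$p,
                                      config$alpha_tildes, config$coeffs,
                                      seed = config$seed)
  Z <- matrix(NA_real_, reps, nrow(entries))
  n_redraws <- 0L
  for (r in seq_len(reps)) {
    attempt <- 0L
    repeat {
      rep_seed <- sub_seed(config$seed, 1000L + r + 100000L * attempt)
      one <- run_one_rep(config, rep_seed, truth = fixed_truth)
      if (one$converged) break
      attempt <- attempt + 1L
      n_redraws <- n_redraws + 1L
      if (n_redraws > 0.1 * reps)
        stop("more than 10% of replications failed to converge",
             call. = FALSE)
    }
    Z[r, ] <- one$result$zscores[entries]
  }
  summ <- data.frame(i = entries[, 1], j = entries[, 2],
                     mean = colMeans(Z), var = apply(Z, 2, stats::var),
                     ks_stat = NA_real_, ks_pvalue = NA_real_)
  for (e in seq_len(nrow(entries))) {
    ks <- suppressWarnings(ks.test(Z[, e], "pnorm"))
    summ$ks_stat[e] <- unname(ks$statistic)
    summ$ks_pvalue[e] <- ks$p.value
  }
  list(samples = Z, summary = summ, n_redraws = n_redraws, config = config)
}

#' @export
print.coverage_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "coverage_report: %s scenario, p = %d, n = %s, %d replications\n",
    cfg$scenario, cfg$p, paste(cfg$n, collapse = "/"), cfg$replications))
  cat(sprintf("  average coverage over S:   %.4f\n", x$avg_S))
  cat(sprintf("  average coverage over S^c: %.4f\n", x$avg_Sc))
  if (x$n_redraws > 0)
    cat(sprintf("  non-converged replications redrawn: %d\n", x$n_redraws))
  invisible(x)
}
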