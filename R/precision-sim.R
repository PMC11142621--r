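#' @title Sparse precision-matrix simulator
#' @description Generates sparse symmetric positive-definite precision
#'   matrices from a random graph, builds the null scenarios used in the
#'   coverage/fluctuation studies, and draws multivariate-normal group
#'   samples from their inverses.
#' @name precision_sim
NULL

# Derive documented RNG substream seeds from one master seed, kept inside
# 32-bit integer range.  Offsets: 1 = graph, 2 = uniform draws, 10 + k =
# matrix k of a scenario, 100 + k = normal sample of group k.
sub_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

#' Generate a random symmetric graph adjacency matrix
#'
#' Selects exactly `round(alpha_tilde * p * (p - 1) / 2)` distinct
#' upper-triangle positions uniformly at random (without replacement) and
#' symmetrizes, so the realized edge proportion is exact rather than
#' Bernoulli-random.
#'
#' @param p Dimension (number of variables), at least 2.
#' @param alpha_tilde Sparsity parameter in \[0, 1\]: the proportion of
#'   off-diagonal entries set to 1.
#' @param seed Integer seed.
#' @return A `p x p` symmetric 0/1 matrix with zero diagonal.
#' @export
generate_graph <- function(p, alpha_tilde, seed = 1L) {
  if (!is.numeric(p) || length(p) != 1L || p < 2)
    stop("`p` must be a single integer >= 2", call. = FALSE)
  if (!is.numeric(alpha_tilde) || alpha_tilde < 0 || alpha_tilde > 1)
    stop("`alpha_tilde` must lie in [0, 1]", call. = FALSE)
  p <- as.integer(p)
  n_pairs <- p * (p - 1L) / 2L
  n_edges <- round(alpha_tilde * n_pairs)
  G <- matrix(0, p, p)
  if (n_edges > 0) {
    set.seed(sub_seed(seed, 1L))
    upper <- which(upper.tri(G))
    sel <- if (n_edges == n_pairs) upper else sample(upper, n_edges)
    G[sel] <- 1
    G <- G + t(G)
  }
  G
}

#' Generate a sparse positive-definite precision matrix
#'
#' For each selected edge (i, j) of the graph, the off-diagonal value is
#' `m = (u_ij + u_ji) / 2` with `u` i.i.d. Uniform(0, 1), shifted by -1 when
#' `m < 0.5` so every nonzero entry has absolute value in \[0.5, 1).
#' Non-edges are exactly 0 and the diagonal of the raw matrix is 0.  The
#' returned precision matrix adds `(|min eigenvalue| + 0.1) I`, which makes it
#' symmetric positive definite with minimum eigenvalue at least 0.1.
#'
#' @inheritParams generate_graph
#' @return A list with components `theta0` (the `p x p` precision matrix),
#'   `theta_tilde` (the raw sparse matrix before the diagonal shift),
#'   `support` (logical `p x p` matrix of nonzero off-diagonal entries),
#'   `s` (support cardinality, counting both (i,j) and (j,i)), `d` (maximum
#'   number of off-diagonal nonzeros in any column), `alpha_tilde`, `seed`.
#' @export
generate_precision <- function(p, alpha_tilde, seed = 1L) {
  G <- generate_graph(p, alpha_tilde, seed)
  p <- nrow(G)
  set.seed(sub_seed(seed, 2L))
  U <- matrix(runif(p * p), p, p)
  M <- (U + t(U)) / 2
  vals <- M - (M < 0.5)
  theta_tilde <- G * vals
  ev_min <- min(eigen(theta_tilde, symmetric = TRUE,
                      only.values = TRUE)$values)
  theta0 <- theta_tilde + (abs(ev_min) + 0.1) * diag(p)
  support <- theta_tilde != 0
  diag(support) <- FALSE
  list(theta0 = theta0, theta_tilde = theta_tilde, support = support,
       s = sum(support), d = max(colSums(support)),
       alpha_tilde = alpha_tilde, seed = seed)
}

#' Build a ground-truth null scenario for multiple groups
#'
#' The three scenarios mirror the simulation designs used to study the
#' de-biased contrast test under its null:
#' * `"equal"`: two identical precision matrices (two-sample equality null);
#'   contrast (1, -1).
#' * `"linear"`: `Theta0[2] = c * Theta0[1]` for a positive constant `c`;
#'   contrast (1, -1/c), whose true value is zero everywhere.
#' * `"three_sample_linear"`: `Theta0[1]`, `Theta0[2]` generated independently
#'   with their own sparsity parameters and
#'   `Theta0[3] = c1 * Theta0[1] + c2 * Theta0[2]`; contrast (c1, c2, -1).
#'
#' Positive coefficients are required so that every combination stays
#' positive definite.  The coverage support `S` is the set of nonzero entries
#' (diagonal included) of the reference combination: `Theta0[1]` for the
#' two-group scenarios, `c1 * Theta0[1] + c2 * Theta0[2]` for three groups.
#'
#' @param scenario One of `"equal"`, `"linear"`, `"three_sample_linear"`.
#' @param p Dimension.
#' @param alpha_tildes Sparsity parameter(s): one value for the two-group
#'   scenarios, two values for `three_sample_linear`.
#' @param coeffs Positive scenario coefficients: none for `"equal"`, one
#'   (`c`) for `"linear"`, two (`c1`, `c2`) for `"three_sample_linear"`.
#' @param seed Integer seed.
#' @return An object of class `sparse_ground_truth`: a list with
#'   `precisions` (list of K matrices), `supports` (list of logical
#'   matrices), `sparsity_param`, `max_row_degree`, `contrast` (the default
#'   null contrast coefficients), `contrast_support` (logical matrix `S`,
#'   diagonal included), `scenario`, `seed`.
#' @export
make_null_scenario <- function(scenario = c("equal", "linear",
                                            "three_sample_linear"),
                               p, alpha_tildes, coeffs = numeric(),
                               seed = 1L) {
  scenario <- match.arg(scenario)
  n_coef <- switch(scenario, equal = 0L, linear = 1L,
                   three_sample_linear = 2L)
  if (length(coeffs) != n_coef)
    stop(sprintf("scenario '%s' needs %d coefficient(s)", scenario, n_coef),
         call. = FALSE)
  if (n_coef > 0 && any(coeffs <= 0))
    stop("scenario coefficients must be positive ",
         "(positive definiteness is otherwise unguaranteed)", call. = FALSE)
  if (scenario == "three_sample_linear") {
    if (length(alpha_tildes) != 2L)
      stop("three_sample_linear needs two alpha_tilde values", call. = FALSE)
    g1 <- generate_precision(p, alpha_tildes[1], sub_seed(seed, 11L))
    g2 <- generate_precision(p, alpha_tildes[2], sub_seed(seed, 12L))
    th3 <- coeffs[1] * g1$theta0 + coeffs[2] * g2$theta0
    precisions <- list(g1$theta0, g2$theta0, th3)
    supports <- list(g1$support, g2$support, th3 != 0 & !diag(p))
    ref <- coeffs[1] * g1$theta0 + coeffs[2] * g2$theta0
    contrast <- c(coeffs, -1)
  } else {
    if (length(alpha_tildes) != 1L)
      stop("two-group scenarios take a single alpha_tilde", call. = FALSE)
    g1 <- generate_precision(p, alpha_tildes, sub_seed(seed, 11L))
    if (scenario == "equal") {
      precisions <- list(g1$theta0, g1$theta0)
      contrast <- c(1, -1)
    } else {
      precisions <- list(g1$theta0, coeffs[1] * g1$theta0)
      contrast <- c(1, -1 / coeffs[1])
    }
    supports <- list(g1$support, g1$support)
    ref <- g1$theta0
  }
  structure(list(precisions = precisions, supports = supports,
                 sparsity_param = alpha_tildes,
                 max_row_degree = vapply(supports, function(s)
                   max(colSums(s)), numeric(1)),
                 contrast = contrast,
                 contrast_support = ref != 0,
                 scenario = scenario, seed = seed),
            class = "sparse_ground_truth")
}

#' Draw multivariate-normal samples for each group
#'
#' Each group k is drawn i.i.d. from N(0, inverse of `Theta0[k]`).
#'
#' @param truth A `sparse_ground_truth` (or a list with a `precisions`
#'   component of positive-definite matrices).
#' @param group_sizes Integer vector of per-group sample sizes (each >= 2).
#' @param seed Integer seed.
#' @return An object of class `group_dataset`: list with `observations`
#'   (list of `n_k x p` matrices), `group_sizes`, `dimension`.
#' @export
sample_groups <- function(truth, group_sizes, seed = 1L) {
  precisions <- truth$precisions
  K <- length(precisions)
  if (length(group_sizes) == 1L) group_sizes <- rep(group_sizes, K)
  if (length(group_sizes) != K)
    stop("`group_sizes` must have one entry per group", call. = FALSE)
  if (any(group_sizes < 2))
    stop("every group size must be at least 2", call. = FALSE)
  p <- nrow(precisions[[1]])
  observations <- vector("list", K)
  for (k in seq_len(K)) {
    ev <- eigen(precisions[[k]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop("precision matrix ", k, " is not positive definite",
           call. = FALSE)
    sigma <- chol2inv(chol(precisions[[k]]))
    sigma <- (sigma + t(sigma)) / 2
    set.seed(sub_seed(seed, 100L + k))
    observations[[k]] <- MASS::mvrnorm(group_sizes[k], mu = rep(0, p),
                                       Sigma = sigma)
  }
  structure(list(observations = observations,
                 group_sizes = as.integer(group_sizes), dimension = p),
            class = "group_dataset")
}

#' @export
print.sparse_ground_truth <- function(x, ...) {
  cat(sprintf(
    "sparse_ground_truth: %d group(s), p = %d, scenario = %s\n",
    length(x$precisions), nrow(x$precisions[[1]]), x$scenario))
  cat(sprintf("  off-diagonal support sizes: %s\n",
              paste(vapply(x$supports, sum, numeric(1)), collapse = ", ")))
  invisible(x)
}

#' @export
print.group_dataset <- function(x, ...) {
  cat(sprintf("group_dataset: %d group(s), p = %d, n = (%s)\n",
              length(x$observations), x$dimension,
              paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}
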