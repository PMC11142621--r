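// ADMM core for the fused graphical lasso.
//
// The K-group objective is
//   sum_k { tr(S_k Theta_k) - logdet(Theta_k) }
//     + lambda * sum_k ||offdiag(Theta_k)||_1
//     + rho * sum_{k<k'} ||offdiag(Theta_k - Theta_k')||_1
// split as Theta_k = Z_k with scaled duals U_k.  The Theta-update has the
// standard eigenvalue closed form; the Z-update is an exact entrywise
// fused-lasso proximal operator (complete-graph total variation reduced to
// isotonic regression, then soft-thresholding); penalties touch off-diagonal
// entries only.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Pool-adjacent-violators for unweighted isotonic regression (ascending).
static void pava(std::vector<double>& y) {
  const int n = (int)y.size();
  std::vector<double> level(n), weight(n);
  std::vector<int> count(n);
  int m = 0;
  for (int i = 0; i < n; ++i) {
    level[m] = y[i]; weight[m] = 1.0; count[m] = 1;
    while (m > 0 && level[m - 1] > level[m]) {
      double w = weight[m - 1] + weight[m];
      level[m - 1] = (weight[m - 1] * level[m - 1] + weight[m] * level[m]) / w;
      weight[m - 1] = w;
      count[m - 1] += count[m];
      --m;
    }
    ++m;
  }
  int pos = 0;
  for (int b = 0; b < m; ++b)
    for (int c = 0; c < count[b]; ++c) y[pos++] = level[b];
}

// Exact proximal operator of
//   (mu/2) * sum_k (z_k - a_k)^2 + lam * sum_k |z_k|
//     + rho * sum_{k<k'} |z_k - z_k'|
// (lam, rho dropped when is_diag).  The fusion prox preserves the ordering of
// a; on sorted values the complete-graph TV term is linear with coefficient
// (2k - 1 - K), so the fusion solution is isotonic regression of the shifted
// sorted values.  Soft-thresholding composes afterwards for the l1 part.
static vec fused_prox_core(const vec& a, double mu, double lam, double rho,
                           bool is_diag) {
  const int K = (int)a.n_elem;
  if (is_diag || (lam == 0.0 && rho == 0.0)) {
    if (is_diag) return a;
  }
  vec z = a;
  if (rho > 0.0 && K > 1) {
    uvec ord = sort_index(a);
    std::vector<double> b(K);
    double tau = rho / mu;
    for (int k = 0; k < K; ++k)
      b[k] = a(ord(k)) - tau * (2.0 * (k + 1) - 1.0 - K);
    pava(b);
    for (int k = 0; k < K; ++k) z(ord(k)) = b[k];
  }
  if (lam > 0.0) {
    double t = lam / mu;
    for (int k = 0; k < K; ++k) z(k) = soft(z(k), t);
  }
  return z;
}

// [[Rcpp::export]]
arma::vec fused_prox_cpp(const arma::vec& a, double mu, double lam,
                         double rho, bool is_diag) {
  return fused_prox_core(a, mu, lam, rho, is_diag);
}

// Apply the fused prox to every entry of a p x p x K cube (diagonal entries
// pass through unchanged).
// [[Rcpp::export]]
arma::cube fused_prox_cube_cpp(const arma::cube& A, double mu, double lam,
                               double rho) {
  const uword p = A.n_rows, K = A.n_slices;
  cube Z(p, p, K);
  vec a(K);
  for (uword j = 0; j < p; ++j) {
    for (uword i = 0; i <= j; ++i) {
      for (uword k = 0; k < K; ++k) a(k) = A(i, j, k);
      vec z = fused_prox_core(a, mu, lam, rho, i == j);
      for (uword k = 0; k < K; ++k) {
        Z(i, j, k) = z(k);
        Z(j, i, k) = z(k);
      }
    }
  }
  return Z;
}

// [[Rcpp::export]]
Rcpp::List admm_fgl_cpp(const arma::cube& S, double lambda, double rho,
                        double mu, int max_iter, double tol_primal,
                        double tol_dual, const arma::cube& Z0,
                        const arma::cube& U0) {
  const uword p = S.n_rows, K = S.n_slices;
  cube Theta(p, p, K), Z = Z0, U = U0, A(p, p, K);
  vec eval;
  mat evec;
  double r = datum::inf, s = datum::inf;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= max_iter; ++it) {
    // Theta-update: minimize tr(S Th) - logdet Th + (mu/2)||Th - Z + U||^2
    for (uword k = 0; k < K; ++k) {
      mat M = mu * (Z.slice(k) - U.slice(k)) - S.slice(k);
      M = 0.5 * (M + M.t());
      eig_sym(eval, evec, M);
      vec th = (eval + sqrt(square(eval) + 4.0 * mu)) / (2.0 * mu);
      Theta.slice(k) = evec * diagmat(th) * evec.t();
    }
    // Z-update: entrywise fused prox on Theta + U
    cube Zold = Z;
    A = Theta + U;
    Z = fused_prox_cube_cpp(A, mu, lambda, rho);
    // dual update
    U += Theta - Z;
    r = 0.0; s = 0.0;
    for (uword k = 0; k < K; ++k) {
      r += accu(square(Theta.slice(k) - Z.slice(k)));
      s += accu(square(Z.slice(k) - Zold.slice(k)));
    }
    r = std::sqrt(r);
    s = mu * std::sqrt(s);
    if (r <= tol_primal && s <= tol_dual) { converged = true; break; }
  }
  if (it > max_iter) it = max_iter;
  return Rcpp::List::create(
      Rcpp::Named("theta") = Theta, Rcpp::Named("z") = Z,
      Rcpp::Named("u") = U, Rcpp::Named("iterations") = it,
      Rcpp::Named("primal_residual") = r, Rcpp::Named("dual_residual") = s,
      Rcpp::Named("converged") = converged);
}
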