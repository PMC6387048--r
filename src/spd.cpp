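// Core numerics for the affine-invariant geometry of SPD matrices.
// All matrix functions go through symmetric eigendecompositions; eigenvalues
// below EIG_RTOL * max trigger an error rather than being clipped.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EIG_RTOL = 1e-12;

static void checked_eig(const mat& S, vec& eval, mat& evec, const char* what) {
  if (!eig_sym(eval, evec, symmatu(S)))
    Rcpp::stop("eigendecomposition failed (%s)", what);
  double mx = eval.max();
  if (mx <= 0.0 || eval.min() < EIG_RTOL * mx)
    Rcpp::stop("matrix is not positive definite within tolerance (%s)", what);
}

static mat sym_logm(const mat& S, const char* what) {
  vec eval; mat evec;
  checked_eig(S, eval, evec, what);
  return evec * diagmat(log(eval)) * evec.t();
}

static mat sym_expm(const mat& S) {
  vec eval; mat evec;
  if (!eig_sym(eval, evec, symmatu(S)))
    Rcpp::stop("eigendecomposition failed (matrix exponential)");
  return evec * diagmat(exp(eval)) * evec.t();
}

// delta(A, B) = sqrt(sum_i log^2 lambda_i), lambda_i generalized eigenvalues
// of (A, B), computed through the Cholesky whitening L^{-1} A L^{-T}.
static double spd_dist(const mat& A, const mat& B) {
  mat L;
  if (!chol(L, B, "lower"))
    Rcpp::stop("matrix is not positive definite (Cholesky failed)");
  mat Y = solve(trimatl(L), A);
  mat W = solve(trimatl(L), Y.t());
  vec eval;
  if (!eig_sym(eval, symmatu(W)))
    Rcpp::stop("eigendecomposition failed (distance)");
  double mx = eval.max();
  if (mx <= 0.0 || eval.min() < EIG_RTOL * mx)
    Rcpp::stop("matrix is not positive definite within tolerance (distance)");
  vec l = log(eval);
  return std::sqrt(accu(square(l)));
}

static std::vector<mat> as_mats(const Rcpp::List& covs) {
  std::vector<mat> out;
  out.reserve(covs.size());
  for (int i = 0; i < covs.size(); ++i)
    out.push_back(Rcpp::as<mat>(covs[i]));
  return out;
}

// [[Rcpp::export]]
double cpp_spd_distance(const arma::mat& a, const arma::mat& b) {
  return spd_dist(a, b);
}

// [[Rcpp::export]]
arma::mat cpp_pairwise_distances(Rcpp::List covs) {
  std::vector<mat> C = as_mats(covs);
  size_t n = C.size();
  mat D(n, n, fill::zeros);
  for (size_t i = 0; i < n; ++i)
    for (size_t j = i + 1; j < n; ++j) {
      double d = spd_dist(C[i], C[j]);
      D(i, j) = d;
      D(j, i) = d;
    }
  return D;
}

// [[Rcpp::export]]
arma::mat cpp_cross_distances(Rcpp::List covs, Rcpp::List refs) {
  std::vector<mat> C = as_mats(covs);
  std::vector<mat> R = as_mats(refs);
  mat D(C.size(), R.size());
  for (size_t j = 0; j < R.size(); ++j) {
    // whiten by the reference once per column
    mat L;
    if (!chol(L, R[j], "lower"))
      Rcpp::stop("reference matrix %d is not positive definite", (int)(j + 1));
    for (size_t i = 0; i < C.size(); ++i) {
      mat Y = solve(trimatl(L), C[i]);
      mat W = solve(trimatl(L), Y.t());
      vec eval;
      if (!eig_sym(eval, symmatu(W)))
        Rcpp::stop("eigendecomposition failed (distance)");
      double mx = eval.max();
      if (mx <= 0.0 || eval.min() < EIG_RTOL * mx)
        Rcpp::stop("matrix %d is not positive definite within tolerance", (int)(i + 1));
      D(i, j) = std::sqrt(accu(square(log(eval))));
    }
  }
  return D;
}

// Fixed-point iteration for the geometric (Frechet) mean, initialized at the
// arithmetic mean.  The residual is the Frobenius norm of the mean log map;
// iteration stops once it falls below tol.
// [[Rcpp::export]]
Rcpp::List cpp_geometric_mean(Rcpp::List covs, double tol, int max_iter) {
  std::vector<mat> C = as_mats(covs);
  int k = (int)C.size();
  if (k == 0) Rcpp::stop("empty covariance set");
  int n = (int)C[0].n_rows;

  mat M(n, n, fill::zeros);
  for (int i = 0; i < k; ++i) M += C[i];
  M /= (double)k;
  M = symmatu(M);

  double resid = datum::inf;
  double prev = datum::inf;
  double nu = 1.0;  // step size; halved whenever the residual grows
  int iter = 0;
  for (; iter <= max_iter; ++iter) {
    vec eval; mat evec;
    checked_eig(M, eval, evec, "geometric mean iterate");
    mat Msq  = evec * diagmat(sqrt(eval)) * evec.t();
    mat Misq = evec * diagmat(1.0 / sqrt(eval)) * evec.t();
    mat S(n, n, fill::zeros);
    for (int i = 0; i < k; ++i) {
      mat W = symmatu(Misq * C[i] * Misq);
      S += sym_logm(W, "geometric mean log map");
    }
    S /= (double)k;
    resid = norm(S, "fro");
    if (resid < tol)
      return Rcpp::List::create(
        Rcpp::Named("mean") = M,
        Rcpp::Named("iterations") = iter,
        Rcpp::Named("final_residual") = resid,
        Rcpp::Named("converged") = true);
    if (iter == max_iter) break;
    // damp oscillation on widely spread sets, recover speed once stable
    if (resid > prev) nu *= 0.5; else nu = std::min(1.0, nu * 1.2);
    prev = resid;
    M = symmatu(Msq * sym_expm(nu * S) * Msq);
  }
  return Rcpp::List::create(
    Rcpp::Named("mean") = M,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("final_residual") = resid,
    Rcpp::Named("converged") = false);
}
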