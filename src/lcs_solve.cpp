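// Batched per-pixel least-squares solves for the implicit retrieval system.
// Each detector pixel contributes K equations in 4 (scalar dark-field) or 6
// (tensor dark-field) unknowns; normal equations with Tikhonov damping are
// solved pixel by pixel.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// coef: list of P matrices (n_pix x K), one per unknown; rhs: n_pix x K.
// lambda: damping added to the normal-equation diagonal (absolute, per
// column scale supplied by the caller as a length-P vector).
// Returns n_pix x (P + 2): solution, rms residual, rank flag (1 = damped
// pseudo-inverse fallback used).
// [[Rcpp::export]]
arma::mat lcs_solve_batch(const List& coef, const arma::mat& rhs,
                          const arma::vec& lambda) {
  const int P = coef.size();
  std::vector<arma::mat> C(P);
  for (int p = 0; p < P; ++p) C[p] = as<arma::mat>(coef[p]);
  const arma::uword n = rhs.n_rows, K = rhs.n_cols;
  arma::mat out(n, P + 2, arma::fill::zeros);
  arma::mat A(K, P);
  arma::vec b(K), x(P);
  for (arma::uword i = 0; i < n; ++i) {
    for (int p = 0; p < P; ++p)
      for (arma::uword k = 0; k < K; ++k) A(k, p) = C[p](i, k);
    for (arma::uword k = 0; k < K; ++k) b(k) = rhs(i, k);
    arma::mat G = A.t() * A;
    G.diag() += lambda;
    arma::vec rbs = A.t() * b;
    bool ok = arma::solve(x, G, rbs, arma::solve_opts::no_approx);
    double flag = 0.0;
    if (!ok || !x.is_finite()) {
      x = arma::pinv(G) * rbs;  // minimum-norm fallback for degenerate pixels
      flag = 1.0;
    }
    arma::vec r = A * x - b;
    for (int p = 0; p < P; ++p) out(i, p) = x(p);
    out(i, P) = std::sqrt(arma::dot(r, r) / K);
    out(i, P + 1) = flag;
  }
  return out;
}

// Solve per-pixel symmetric P x P normal systems given the packed
// upper-triangular products G (n x P(P+1)/2, column order (1,1),(1,2),...,
// (1,P),(2,2),...) and right-hand sides B (n x P).
// [[Rcpp::export]]
arma::mat solve_normal_batch(const arma::mat& G, const arma::mat& B,
                             const arma::vec& lambda) {
  const arma::uword n = B.n_rows;
  const int P = B.n_cols;
  arma::mat out(n, P + 1, arma::fill::zeros);
  arma::mat A(P, P);
  arma::vec b(P), x(P);
  for (arma::uword i = 0; i < n; ++i) {
    int q = 0;
    for (int r = 0; r < P; ++r)
      for (int c = r; c < P; ++c) {
        A(r, c) = G(i, q);
        A(c, r) = G(i, q);
        ++q;
      }
    for (int r = 0; r < P; ++r) { A(r, r) += lambda(r); b(r) = B(i, r); }
    bool ok = arma::solve(x, A, b, arma::solve_opts::likely_sympd +
                                    arma::solve_opts::no_approx);
    double flag = 0.0;
    if (!ok || !x.is_finite()) {
      x = arma::pinv(A) * b;
      flag = 1.0;
    }
    for (int r = 0; r < P; ++r) out(i, r) = x(r);
    out(i, P) = flag;
  }
  return out;
}
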