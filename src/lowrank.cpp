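// Profiled maximum-likelihood objective and gradient for the low-rank
// three-component LMM, evaluated in the kinship eigenbasis:
//   V = exp(t1) * diag(S) + exp(t2) * G G' + I      (noise scale profiled)
//   nll(t) = n/2 (log 2pi + 1) + n/2 log(RSS/n) + log|V| / 2
// with RSS = min_alpha (y - C alpha)' V^{-1} (y - C alpha).
// Woodbury solves keep the cost at O(N R^2) per evaluation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List lowrank_nll_grad_cpp(const arma::vec& theta, const arma::vec& yr,
                                const arma::mat& Cr, const arma::mat& G,
                                const arma::vec& S) {
  const double e1 = std::exp(theta(0)), e2 = std::exp(theta(1));
  const uword n = yr.n_elem, p = Cr.n_cols, r = G.n_cols;
  vec d = e1 * S + 1.0;
  mat A = G * std::sqrt(e2);
  mat Ad = A.each_col() / d;
  mat M = eye(r, r) + A.t() * Ad;
  M = 0.5 * (M + M.t());
  mat ch = chol(M, "lower");
  // W = D^{-1} A L^{-T} (M = L L'), so V^{-1} = D^{-1} - W W'
  mat W = solve(trimatl(ch), Ad.t()).t();
  double logdet = sum(log(d)) + 2.0 * sum(log(ch.diag()));

  mat B = join_rows(Cr, yr);
  mat VB = B.each_col() / d;
  VB -= W * (W.t() * B);
  mat VC = VB.cols(0, p - 1);
  vec Vy = VB.col(p);
  mat CtVC = Cr.t() * VC;
  vec CtVy = Cr.t() * Vy;
  vec alpha = solve(CtVC, CtVy);
  double rss = dot(yr, Vy) - dot(CtVy, alpha);
  if (!(rss > 0.0) || !std::isfinite(rss)) {
    return Rcpp::List::create(Rcpp::Named("value") = 1e10,
                              Rcpp::Named("grad") =
                                  Rcpp::NumericVector::create(0.0, 0.0));
  }

  double nll = 0.5 * n * (std::log(2.0 * M_PI) + 1.0) +
               0.5 * n * std::log(rss / n) + 0.5 * logdet;

  vec rr = yr - Cr * alpha;
  vec u = rr / d - W * (W.t() * rr);
  double g1_rss = -e1 * dot(u % S, u);
  vec Gu = G.t() * u;
  double g2_rss = -e2 * dot(Gu, Gu);
  vec diagVinv = 1.0 / d - sum(square(W), 1);
  double tr1 = e1 * dot(S, diagVinv);
  mat VG = G.each_col() / d;
  VG -= W * (W.t() * G);
  double tr2 = e2 * accu(G % VG);
  Rcpp::NumericVector grad = Rcpp::NumericVector::create(
      0.5 * n * g1_rss / rss + 0.5 * tr1,
      0.5 * n * g2_rss / rss + 0.5 * tr2);
  return Rcpp::List::create(Rcpp::Named("value") = nll,
                            Rcpp::Named("grad") = grad);
}
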