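// Gradient-projection oblique rotation (quartimin criterion).
// Mirrors the reference R implementation in R/gca-factor.R; the R version
// is kept as the correctness oracle in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double quartimin_f(const mat& L, const mat& N, mat& Gq) {
  mat L2 = square(L);
  mat X = L2 * N;
  Gq = L % X;
  return accu(L2 % X) / 4.0;
}

// [[Rcpp::export(name = ".gpa_oblq_cpp")]]
Rcpp::List gpa_oblq_cpp(const arma::mat& A, const arma::mat& T0,
                        int maxit, double eps) {
  const uword m = A.n_cols;
  mat N = ones<mat>(m, m) - eye<mat>(m, m);
  mat Tmat = T0;
  double al = 1.0;
  mat Ti = inv(Tmat);
  mat L = A * Ti.t();
  mat Gq;
  double f = quartimin_f(L, N, Gq);
  mat G = -trans((L.t() * Gq) * Ti);
  mat Tt = Tmat, Lt = L, Gqt;
  for (int iter = 0; iter < maxit; ++iter) {
    rowvec d = sum(Tmat % G, 0);
    mat Gp = G - Tmat % repmat(d, m, 1);
    double s = std::sqrt(accu(Gp % Gp));
    if (s < eps) break;
    al *= 2.0;
    double ft = f;
    for (int i = 0; i <= 12; ++i) {
      mat X = Tmat - al * Gp;
      rowvec v = 1.0 / sqrt(sum(X % X, 0));
      Tt = X % repmat(v, m, 1);
      mat Tti = inv(Tt);
      Lt = A * Tti.t();
      ft = quartimin_f(Lt, N, Gqt);
      if (ft < f - 0.5 * s * s * al) {
        Ti = Tti;
        break;
      }
      Ti = Tti;
      al /= 2.0;
    }
    Tmat = Tt;
    L = Lt;
    f = ft;
    G = -trans((L.t() * Gqt) * Ti);
  }
  return Rcpp::List::create(Rcpp::Named("loadings") = L,
                            Rcpp::Named("Phi") = Tmat.t() * Tmat,
                            Rcpp::Named("f") = f);
}
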