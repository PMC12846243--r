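// Element-wise layers in C++: instance norm and PReLU/LeakyReLU dominate
// the R-side profile otherwise (aperm/sweep allocations).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double IN_EPS = 1e-5;

// x: (C, L, B).  Returns y plus the xhat/istd cache for backward.
// [[Rcpp::export]]
Rcpp::List inorm_fw_cpp(const arma::cube& x, const arma::vec& gamma,
                        const arma::vec& beta) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  cube y(C, L, B), xhat(C, L, B);
  mat istd(C, B);
  for (int s = 0; s < B; ++s) {
    const mat& xs = x.slice(s);
    vec mu = mean(xs, 1);
    vec va = mean(square(xs), 1) - square(mu);
    va.transform([](double v) { return v > 0 ? v : 0.0; });
    vec is = 1.0 / sqrt(va + IN_EPS);
    mat xh = xs.each_col() - mu;
    xh.each_col() %= is;
    xhat.slice(s) = xh;
    mat ys = xh.each_col() % gamma;
    ys.each_col() += beta;
    y.slice(s) = ys;
    istd.col(s) = is;
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::List inorm_bw_cpp(const arma::cube& xhat, const arma::mat& istd,
                        const arma::vec& gamma, const arma::cube& gout) {
  const int C = xhat.n_rows, L = xhat.n_cols, B = xhat.n_slices;
  cube gx(C, L, B);
  vec ggamma(C, fill::zeros), gbeta(C, fill::zeros);
  for (int s = 0; s < B; ++s) {
    const mat& gs = gout.slice(s);
    const mat& xh = xhat.slice(s);
    mat gxh = gs.each_col() % gamma;
    vec s1 = mean(gxh, 1);
    vec s2 = mean(gxh % xh, 1);
    mat g = gxh;
    g.each_col() -= s1;
    g -= xh.each_col() % s2;
    g.each_col() %= istd.col(s);
    gx.slice(s) = g;
    ggamma += sum(gs % xh, 1);
    gbeta += sum(gs, 1);
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("ggamma") = ggamma,
                            Rcpp::Named("gbeta") = gbeta);
}

// [[Rcpp::export]]
arma::cube prelu_fw_cpp(const arma::cube& x, const arma::vec& a) {
  cube y = x;
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < L; ++t) {
      for (int c = 0; c < C; ++c) {
        double v = x(c, t, s);
        if (v < 0) y(c, t, s) = a(c) * v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List prelu_bw_cpp(const arma::cube& x, const arma::vec& a,
                        const arma::cube& gout) {
  const int C = x.n_rows, L = x.n_cols, B = x.n_slices;
  cube gx(C, L, B);
  vec ga(C, fill::zeros);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < L; ++t) {
      for (int c = 0; c < C; ++c) {
        double v = x(c, t, s), g = gout(c, t, s);
        if (v > 0) {
          gx(c, t, s) = g;
        } else {
          gx(c, t, s) = a(c) * g;
          ga(c) += g * v;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx, Rcpp::Named("ga") = ga);
}

// [[Rcpp::export]]
arma::cube lrelu_fw_cpp(const arma::cube& x, double slope) {
  cube y = x;
  y.transform([slope](double v) { return v > 0 ? v : slope * v; });
  return y;
}

// [[Rcpp::export]]
arma::cube lrelu_bw_cpp(const arma::cube& x, const arma::cube& gout,
                        double slope) {
  cube gx = gout;
  const uword n = x.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (x(i) <= 0) gx(i) *= slope;
  }
  return gx;
}
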