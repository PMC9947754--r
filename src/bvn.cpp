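#include <Rcpp.h>
#include "bvn.h"
using namespace Rcpp;

static inline double recycled(const NumericVector& v, R_xlen_t i) {
  return v[i % v.size()];
}

// [[Rcpp::export]]
NumericVector C_bvn_cdf(NumericVector a, NumericVector b, NumericVector rho) {
  R_xlen_t n = std::max(a.size(), std::max(b.size(), rho.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    double r = recycled(rho, i);
    double ai = recycled(a, i), bi = recycled(b, i);
    if (ISNAN(ai) || ISNAN(bi) || ISNAN(r)) { out[i] = NA_REAL; continue; }
    out[i] = gbp_bvn_cdf(ai, bi, r);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector C_bvn_pdf(NumericVector a, NumericVector b, NumericVector rho) {
  R_xlen_t n = std::max(a.size(), std::max(b.size(), rho.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = gbp_bvn_pdf(recycled(a, i), recycled(b, i), recycled(rho, i));
  return out;
}

// Four-cell probabilities of the bivariate probit by inclusion-exclusion.
// Returns an n x 4 matrix with columns p11, p10, p01, p00.
// [[Rcpp::export]]
NumericMatrix C_cell_probs(NumericVector mu1, NumericVector mu2,
                           NumericVector rho) {
  R_xlen_t n = std::max(mu1.size(), std::max(mu2.size(), rho.size()));
  NumericMatrix out(n, 4);
  for (R_xlen_t i = 0; i < n; i++) {
    double m1 = recycled(mu1, i), m2 = recycled(mu2, i), r = recycled(rho, i);
    double ph1 = R::pnorm(m1, 0.0, 1.0, 1, 0);
    double ph2 = R::pnorm(m2, 0.0, 1.0, 1, 0);
    double p11 = gbp_bvn_cdf(m1, m2, r);
    double p10 = ph1 - p11;
    double p01 = ph2 - p11;
    double p00 = 1.0 - ph1 - ph2 + p11;
    out(i, 0) = p11;
    out(i, 1) = (p10 < 0.0) ? 0.0 : p10;
    out(i, 2) = (p01 < 0.0) ? 0.0 : p01;
    out(i, 3) = (p00 < 0.0) ? 0.0 : p00;
  }
  return out;
}

// [[Rcpp::export]]
double C_loglik(IntegerVector y1, IntegerVector y2, NumericVector eta1,
                NumericVector eta2, NumericVector etarho) {
  R_xlen_t n = y1.size();
  double ll = 0.0;
  for (R_xlen_t i = 0; i < n; i++) {
    double r = std::tanh(etarho[i]);
    if (r > 1.0 - 1e-10) r = 1.0 - 1e-10;
    if (r < -1.0 + 1e-10) r = -1.0 + 1e-10;
    double m1 = eta1[i], m2 = eta2[i];
    double ph1 = R::pnorm(m1, 0.0, 1.0, 1, 0);
    double ph2 = R::pnorm(m2, 0.0, 1.0, 1, 0);
    double p11 = gbp_bvn_cdf(m1, m2, r);
    double p;
    if (y1[i] == 1 && y2[i] == 1) p = p11;
    else if (y1[i] == 1) p = ph1 - p11;
    else if (y2[i] == 1) p = ph2 - p11;
    else p = 1.0 - ph1 - ph2 + p11;
    if (p < 1e-300) p = 1e-300;
    ll += std::log(p);
  }
  return ll;
}
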