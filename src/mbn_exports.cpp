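#include <Rcpp.h>
#include "mbn.h"
using namespace Rcpp;

// Vectorised log pmf; inputs are pre-recycled to a common length in R.
// [[Rcpp::export(name = "mbn_logpmf_cpp")]]
NumericVector mbn_logpmf_cpp(IntegerVector x, IntegerVector nb,
                             NumericVector phi, NumericVector theta) {
  int n = x.size(), mx = 0;
  for (int i = 0; i < n; ++i) if (nb[i] > mx) mx = nb[i];
  if (mx > MBN_MAX_NB) stop("litter size above supported maximum (%d)", MBN_MAX_NB);
  LchooseTable lch(mx);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double lp = std::log(phi[i]), l1p = std::log1p(-phi[i]);
    out[i] = mbn_log_pmf(x[i], nb[i], lp, l1p, std::log(theta[i]), lch);
  }
  return out;
}

// K_{nb-a}(phi, theta) on the natural scale.
// [[Rcpp::export(name = "mbn_normalizer_cpp")]]
NumericVector mbn_normalizer_cpp(IntegerVector nb, NumericVector phi,
                                 NumericVector theta, int a) {
  int n = nb.size(), mx = 0;
  for (int i = 0; i < n; ++i) if (nb[i] > mx) mx = nb[i];
  if (mx > MBN_MAX_NB) stop("litter size above supported maximum (%d)", MBN_MAX_NB);
  LchooseTable lch(mx);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double lp = std::log(phi[i]), l1p = std::log1p(-phi[i]);
    out[i] = std::exp(mbn_log_normalizer(nb[i], a, lp, l1p, std::log(theta[i]), lch));
  }
  return out;
}

// Exact sampling by CDF inversion over the enumerated pmf.
// Uses R's RNG so draws are reproducible from set.seed().
// [[Rcpp::export(name = "mbn_sample_cpp")]]
IntegerVector mbn_sample_cpp(IntegerVector nb, NumericVector phi,
                             NumericVector theta) {
  int n = nb.size(), mx = 0;
  for (int i = 0; i < n; ++i) if (nb[i] > mx) mx = nb[i];
  if (mx > MBN_MAX_NB) stop("litter size above supported maximum (%d)", MBN_MAX_NB);
  LchooseTable lch(mx);
  IntegerVector out(n);
  double pr[MBN_MAX_NB + 1];
  for (int i = 0; i < n; ++i) {
    int m = nb[i];
    if (m == 0) { out[i] = 0; continue; }
    double lp = std::log(phi[i]), l1p = std::log1p(-phi[i]);
    double lth = std::log(theta[i]);
    double logK = mbn_log_normalizer(m, 0, lp, l1p, lth, lch);
    const double *lc = lch.row(m);
    for (int x = 0; x <= m; ++x)
      pr[x] = std::exp(lc[x] + x * lp + (m - x) * l1p
                       + ((double) x) * (m - x) * lth - logK);
    double u = unif_rand(), acc = 0.0;
    int draw = m;
    for (int x = 0; x <= m; ++x) {
      acc += pr[x];
      if (u <= acc) { draw = x; break; }
    }
    out[i] = draw;
  }
  return out;
}
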