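#ifndef MBNDIALLEL_MBN_H
#define MBNDIALLEL_MBN_H

#include <R.h>
#include <Rmath.h>
#include <cmath>
#include <vector>

// Litter sizes in this domain are small (nb <~ 30); 256 is a hard safety cap
// for the stack buffers used in the normalizer sums.
#define MBN_MAX_NB 256

// Cache of log binomial coefficients; row n holds lchoose(n, 0..n).
class LchooseTable {
  std::vector< std::vector<double> > rows;
public:
  explicit LchooseTable(int max_n) : rows(max_n + 1) {
    for (int n = 0; n <= max_n; ++n) {
      rows[n].resize(n + 1);
      for (int k = 0; k <= n; ++k)
        rows[n][k] = Rf_lchoose((double) n, (double) k);
    }
  }
  int max_n() const { return (int) rows.size() - 1; }
  const double *row(int n) const { return rows[n].data(); }
};

// Stable log(phi), log(1-phi) from the logit.
inline void mbn_logit_to_logphi(double lgt, double &logphi, double &log1mphi) {
  logphi   = -log1p(std::exp(-lgt));
  log1mphi = -log1p(std::exp(lgt));
}

// log K_{nb-a}(phi, theta) =
//   log sum_{j=0}^{nb-a} C(nb-a, j) phi^j (1-phi)^(nb-a-j) theta^{(j+a)(nb-a-j)}
// computed by log-sum-exp; a is 0 for K_nb and 1 for K_{nb-1}.
inline double mbn_log_normalizer(int nb, int a, double logphi, double log1mphi,
                                 double logtheta, const LchooseTable &lch) {
  const int m = nb - a;
  const double *lc = lch.row(m);
  double term[MBN_MAX_NB + 1];
  double mx = R_NegInf;
  for (int j = 0; j <= m; ++j) {
    double lt = lc[j] + j * logphi + (m - j) * log1mphi
      + ((double) (j + a)) * (m - j) * logtheta;
    term[j] = lt;
    if (lt > mx) mx = lt;
  }
  double s = 0.0;
  for (int j = 0; j <= m; ++j) s += std::exp(term[j] - mx);
  return mx + std::log(s);
}

// log MBN(x | nb, phi, theta), phi given on the log scale.
inline double mbn_log_pmf(int x, int nb, double logphi, double log1mphi,
                          double logtheta, const LchooseTable &lch) {
  double logK = mbn_log_normalizer(nb, 0, logphi, log1mphi, logtheta, lch);
  return lch.row(nb)[x] + x * logphi + (nb - x) * log1mphi
    + ((double) x) * (nb - x) * logtheta - logK;
}

// Convenience overload taking the logit of phi.
inline double mbn_log_pmf_logit(int x, int nb, double lgt, double logtheta,
                                const LchooseTable &lch) {
  double lp, l1p;
  mbn_logit_to_logphi(lgt, lp, l1p);
  return mbn_log_pmf(x, nb, lp, l1p, logtheta, lch);
}

#endif
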