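// Gibbs sampler with adaptive Metropolis-Hastings steps for the recursive
// multiplicative-binomial hierarchical model:
//   t_i  = x_i' b_t + u_t[sow] + p_t[sow] + e_i,            e_i ~ N(0, sigma2_et)
//   y_i ~ MBN(t_i, phi_i, theta),  logit(phi_i) = x_i' b_l + u_l[sow] + p_l[sow]
//          + lambda1[g1(i)] * d_i + lambda2[g2(i)] * d_i^2,  d_i = t_i - tbar
//   (u_l, u_t) ~ N(0, A (x) G),  (p_l, p_t) ~ N(0, I (x) P)
// Flat priors within bounds on b, lambda, G, P, sigma2_et, theta.
//
// Gaussian-side location effects use exact scalar Gibbs conditionals; the
// logit-side effects, lambdas and log(theta) use single-site random-walk MH
// with Robbins-Monro adaptation of proposal sds toward 0.44 acceptance during
// burn-in.  All randomness flows through R's RNG (norm_rand/unif_rand/rchisq)
// so a chain is bitwise reproducible from set.seed().

#include <Rcpp.h>
#include "mbn.h"
using namespace Rcpp;

namespace {

struct ColList {           // nonzero pattern of one design-matrix column
  std::vector<int> rec;
  std::vector<double> val;
  double sumsq = 0.0;
};

// 2x2 symmetric matrices stored as (m11, m12, m22)
inline bool inv2(const double m[3], double out[3]) {
  double det = m[0] * m[2] - m[1] * m[1];
  if (!(det > 0.0) || !(m[0] > 0.0)) return false;
  out[0] = m[2] / det; out[1] = -m[1] / det; out[2] = m[0] / det;
  return true;
}

// One inverse-Wishart draw G ~ IW(df, S) via the Bartlett decomposition of
// W = G^{-1} ~ Wishart(df, S^{-1}); returns false if S^{-1} has no Cholesky.
inline bool riwish2(double df, const double S[3], double out[3]) {
  double V[3];
  if (!inv2(S, V)) return false;
  double l11 = std::sqrt(V[0]);
  double l21 = V[1] / l11;
  double l22sq = V[2] - l21 * l21;
  if (!(l22sq > 0.0)) return false;
  double l22 = std::sqrt(l22sq);
  double a11 = std::sqrt(R::rchisq(df));
  double a22 = std::sqrt(R::rchisq(df - 1.0));
  double a21 = norm_rand();
  double b11 = l11 * a11;
  double b21 = l21 * a11 + l22 * a21;
  double b22 = l22 * a22;
  double W[3] = { b11 * b11, b11 * b21, b21 * b21 + b22 * b22 };
  return inv2(W, out);
}

inline double clamp(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

} // namespace

// [[Rcpp::export(name = "run_chain_cpp")]]
List run_chain_cpp(IntegerVector y, IntegerVector t, NumericVector traw,
                   NumericVector d, IntegerVector cross,
                   IntegerVector sow_ped, IntegerVector sow_pe,
                   NumericMatrix X,
                   IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                   int q_u, int q_p, int model, List init, List ctrl) {
  const int n = y.size();
  const int p = X.ncol();

  // ---- model structure: recursion coefficient groups ------------------
  const int n_g1 = (model >= 2) ? ((model == 4 || model == 5) ? 9 : 1) : 0;
  const int n_g2 = (model == 3) ? 1 : ((model == 5) ? 9 : 0);
  std::vector<int> g1(n, 0), g2(n, 0);
  for (int r = 0; r < n; ++r) {
    if (n_g1 == 9) g1[r] = cross[r] - 1;
    if (n_g2 == 9) g2[r] = cross[r] - 1;
  }

  // ---- control --------------------------------------------------------
  const int n_iter  = as<int>(ctrl["n_iter"]);
  const int burn_in = as<int>(ctrl["burn_in"]);
  const int thin    = as<int>(ctrl["thin"]);
  const double var_lo = as<double>(ctrl["var_lo"]);
  const double var_hi = as<double>(ctrl["var_hi"]);
  const double th_lo  = as<double>(ctrl["theta_lo"]);
  const double th_hi  = as<double>(ctrl["theta_hi"]);
  const double min_sd = as<double>(ctrl["min_sd"]);
  const int max_tries = as<int>(ctrl["max_var_tries"]);
  const bool upd_b_t   = as<bool>(ctrl["update_b_t"]);
  const bool upd_b_l   = as<bool>(ctrl["update_b_l"]);
  const bool upd_u_t   = as<bool>(ctrl["update_u_t"]);
  const bool upd_u_l   = as<bool>(ctrl["update_u_l"]);
  const bool upd_p_t   = as<bool>(ctrl["update_p_t"]);
  const bool upd_p_l   = as<bool>(ctrl["update_p_l"]);
  const bool upd_lam   = as<bool>(ctrl["update_lambda"]);
  const bool upd_G     = as<bool>(ctrl["update_G"]);
  const bool upd_P     = as<bool>(ctrl["update_P"]);
  const bool upd_se    = as<bool>(ctrl["update_sigma_e"]);
  const bool upd_th    = as<bool>(ctrl["update_theta"]);
  const bool store_ll  = as<bool>(ctrl["store_loglik"]);
  const bool store_eff = as<bool>(ctrl["store_effects"]);

  // ---- state ----------------------------------------------------------
  std::vector<double> b_t = as< std::vector<double> >(init["b_t"]);
  std::vector<double> b_l = as< std::vector<double> >(init["b_l"]);
  std::vector<double> u_t = as< std::vector<double> >(init["u_t"]);
  std::vector<double> u_l = as< std::vector<double> >(init["u_l"]);
  std::vector<double> p_t = as< std::vector<double> >(init["p_t"]);
  std::vector<double> p_l = as< std::vector<double> >(init["p_l"]);
  std::vector<double> lam1 = as< std::vector<double> >(init["lambda1"]);
  std::vector<double> lam2 = as< std::vector<double> >(init["lambda2"]);
  NumericVector G0 = init["G"], P0 = init["P"];
  double G[3] = { G0[0], G0[1], G0[2] };
  double P[3] = { P0[0], P0[1], P0[2] };
  double sig2e = as<double>(init["sigma2_et"]);
  double theta = as<double>(init["theta"]);
  double logtheta = std::log(theta);

  double Ginv[3], Pinv[3];
  if (!inv2(G, Ginv)) stop("initial G is not positive definite");
  if (!inv2(P, Pinv)) stop("initial P is not positive definite");

  // ---- precomputed structures -----------------------------------------
  int max_t = 0;
  for (int r = 0; r < n; ++r) if (t[r] > max_t) max_t = t[r];
  if (max_t > MBN_MAX_NB) stop("litter size above supported maximum");
  LchooseTable lch(max_t);

  std::vector<ColList> cols(p);
  for (int j = 0; j < p; ++j)
    for (int r = 0; r < n; ++r) {
      double v = X(r, j);
      if (v != 0.0) {
        cols[j].rec.push_back(r);
        cols[j].val.push_back(v);
        cols[j].sumsq += v * v;
      }
    }

  std::vector< std::vector<int> > rec_ped(q_u), rec_pe(q_p);
  for (int r = 0; r < n; ++r) {
    rec_ped[sow_ped[r] - 1].push_back(r);
    rec_pe[sow_pe[r] - 1].push_back(r);
  }
  std::vector< std::vector<int> > rec_g1(n_g1 ? n_g1 : 1),
                                  rec_g2(n_g2 ? n_g2 : 1);
  if (n_g1) for (int r = 0; r < n; ++r) rec_g1[g1[r]].push_back(r);
  if (n_g2) for (int r = 0; r < n; ++r) rec_g2[g2[r]].push_back(r);

  std::vector<double> d2(n);
  for (int r = 0; r < n; ++r) d2[r] = d[r] * d[r];

  // ---- running caches -------------------------------------------------
  std::vector<double> eta_t(n), lgt(n), ll(n), prop_ll(n);
  std::vector<double> prop_ll_theta(n);
  for (int r = 0; r < n; ++r) {
    double et = 0.0, el = 0.0;
    for (int j = 0; j < p; ++j) {
      double v = X(r, j);
      if (v != 0.0) { et += v * b_t[j]; el += v * b_l[j]; }
    }
    et += u_t[sow_ped[r] - 1] + p_t[sow_pe[r] - 1];
    el += u_l[sow_ped[r] - 1] + p_l[sow_pe[r] - 1];
    if (n_g1) el += lam1[g1[r]] * d[r];
    if (n_g2) el += lam2[g2[r]] * d2[r];
    eta_t[r] = et;
    lgt[r] = el;
    ll[r] = mbn_log_pmf_logit(y[r], t[r], el, logtheta, lch);
  }

  // ---- adaptive proposal sds ------------------------------------------
  std::vector<double> lsd_bl(p, std::log(as<double>(ctrl["sd_b_l"])));
  std::vector<double> lsd_ul(q_u, std::log(as<double>(ctrl["sd_u_l"])));
  std::vector<double> lsd_pl(q_p, std::log(as<double>(ctrl["sd_p_l"])));
  std::vector<double> lsd_lam(n_g1 + n_g2, std::log(as<double>(ctrl["sd_lambda"])));
  double lsd_th = std::log(as<double>(ctrl["sd_log_theta"]));
  const double lsd_min = std::log(min_sd), lsd_max = std::log(50.0);
  const double target_acc = 0.44;

  // post-adaptation acceptance bookkeeping per block
  double acc_bl = 0, try_bl = 0, acc_ul = 0, try_ul = 0,
         acc_pl = 0, try_pl = 0, acc_lam = 0, try_lam = 0,
         acc_th = 0, try_th = 0;

  // ---- output ---------------------------------------------------------
  const int n_keep = (n_iter > burn_in) ? (n_iter - burn_in) / thin : 0;
  const int n_par = 2 * p + n_g1 + n_g2 + 3 + 3 + 1 + 1
    + (store_eff ? 2 * (q_u + q_p) : 0);
  NumericMatrix draws(n_keep, n_par);
  NumericMatrix eff_mean(q_u + q_p, 2);   // posterior means of (l, t) effects
  NumericMatrix loglik(store_ll ? n : 0, store_ll ? n_keep : 0);
  int kept = 0;

  // MH proposal for a set of records whose logit shifts by coef*delta.
  // Returns the log-likelihood difference and fills prop_ll for the set.
  auto delta_loglik = [&](const std::vector<int> &recs,
                          const std::vector<double> *coef,
                          double delta, double scale2) -> double {
    double dll = 0.0;
    for (size_t k = 0; k < recs.size(); ++k) {
      int r = recs[k];
      double shift = coef ? (*coef)[k] * delta
                          : (scale2 == 1.0 ? d[r] : d2[r]) * delta;
      double nl = mbn_log_pmf_logit(y[r], t[r], lgt[r] + shift, logtheta, lch);
      prop_ll[r] = nl;
      dll += nl - ll[r];
    }
    return dll;
  };
  auto apply_shift = [&](const std::vector<int> &recs,
                         const std::vector<double> *coef,
                         double delta, double scale2) {
    for (size_t k = 0; k < recs.size(); ++k) {
      int r = recs[k];
      double shift = coef ? (*coef)[k] * delta
                          : (scale2 == 1.0 ? d[r] : d2[r]) * delta;
      lgt[r] += shift;
      ll[r] = prop_ll[r];
    }
  };

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = iter <= burn_in;
    const double gamma = std::min(0.5, 3.0 / std::pow((double) iter, 0.6));

    // ================= Gaussian side: exact scalar Gibbs ================
    if (upd_b_t) {
      for (int j = 0; j < p; ++j) {
        const ColList &c = cols[j];
        if (c.rec.empty()) continue;           // unobserved level, flat prior
        double sxr = 0.0;
        for (size_t k = 0; k < c.rec.size(); ++k) {
          int r = c.rec[k];
          sxr += c.val[k] * (traw[r] - eta_t[r] + c.val[k] * b_t[j]);
        }
        double mean = sxr / c.sumsq;
        double newb = mean + norm_rand() * std::sqrt(sig2e / c.sumsq);
        double dlt = newb - b_t[j];
        b_t[j] = newb;
        for (size_t k = 0; k < c.rec.size(); ++k)
          eta_t[c.rec[k]] += c.val[k] * dlt;
      }
    }

    if (upd_u_t) {
      for (int i = 0; i < q_u; ++i) {
        double s_t = 0.0, s_l = 0.0, aii = 0.0;
        for (int k = Ap[i]; k < Ap[i + 1]; ++k) {
          int row = Ai[k];
          s_t += Ax[k] * u_t[row];
          s_l += Ax[k] * u_l[row];
          if (row == i) aii = Ax[k];
        }
        const std::vector<int> &recs = rec_ped[i];
        double sumr = 0.0;
        for (size_t k = 0; k < recs.size(); ++k) {
          int r = recs[k];
          sumr += traw[r] - eta_t[r] + u_t[i];
        }
        double prec = recs.size() / sig2e + aii * Ginv[2];
        double num = sumr / sig2e
          - (Ginv[2] * (s_t - aii * u_t[i]) + Ginv[1] * s_l);
        double newu = num / prec + norm_rand() / std::sqrt(prec);
        double dlt = newu - u_t[i];
        u_t[i] = newu;
        for (size_t k = 0; k < recs.size(); ++k) eta_t[recs[k]] += dlt;
      }
    }

    if (upd_p_t) {
      for (int i = 0; i < q_p; ++i) {
        const std::vector<int> &recs = rec_pe[i];
        double sumr = 0.0;
        for (size_t k = 0; k < recs.size(); ++k) {
          int r = recs[k];
          sumr += traw[r] - eta_t[r] + p_t[i];
        }
        double prec = recs.size() / sig2e + Pinv[2];
        double num = sumr / sig2e - Pinv[1] * p_l[i];
        double newp = num / prec + norm_rand() / std::sqrt(prec);
        double dlt = newp - p_t[i];
        p_t[i] = newp;
        for (size_t k = 0; k < recs.size(); ++k) eta_t[recs[k]] += dlt;
      }
    }

    // ================= logit side: single-site random-walk MH ===========
    if (upd_b_l) {
      for (int j = 0; j < p; ++j) {
        const ColList &c = cols[j];
        if (c.rec.empty()) continue;           // flat prior, no data: skip
        double delta = std::exp(lsd_bl[j]) * norm_rand();
        double dll = delta_loglik(c.rec, &c.val, delta, 1.0);
        double alpha = dll >= 0.0 ? 1.0 : std::exp(dll);
        if (unif_rand() < alpha) {
          b_l[j] += delta;
          apply_shift(c.rec, &c.val, delta, 1.0);
          if (!adapting) acc_bl += 1;
        }
        if (!adapting) try_bl += 1;
        if (adapting)
          lsd_bl[j] = clamp(lsd_bl[j] + gamma * (alpha - target_acc),
                            lsd_min, lsd_max);
      }
    }

    if (upd_u_l) {
      for (int i = 0; i < q_u; ++i) {
        double s_t = 0.0, s_l = 0.0, aii = 0.0;
        for (int k = Ap[i]; k < Ap[i + 1]; ++k) {
          int row = Ai[k];
          s_t += Ax[k] * u_t[row];
          s_l += Ax[k] * u_l[row];
          if (row == i) aii = Ax[k];
        }
        double delta = std::exp(lsd_ul[i]) * norm_rand();
        double unew = u_l[i] + delta;
        // prior log-density change for (u_l, u_t) ~ N(0, A (x) G)
        double dprior = -0.5 * Ginv[0] * aii * (unew * unew - u_l[i] * u_l[i])
          - delta * (Ginv[0] * (s_l - aii * u_l[i]) + Ginv[1] * s_t);
        const std::vector<int> &recs = rec_ped[i];
        double dll = dprior;
        for (size_t k = 0; k < recs.size(); ++k) {
          int r = recs[k];
          double nl = mbn_log_pmf_logit(y[r], t[r], lgt[r] + delta, logtheta, lch);
          prop_ll[r] = nl;
          dll += nl - ll[r];
        }
        double alpha = dll >= 0.0 ? 1.0 : std::exp(dll);
        if (unif_rand() < alpha) {
          u_l[i] = unew;
          for (size_t k = 0; k < recs.size(); ++k) {
            int r = recs[k];
            lgt[r] += delta;
            ll[r] = prop_ll[r];
          }
          if (!adapting) acc_ul += 1;
        }
        if (!adapting) try_ul += 1;
        if (adapting)
          lsd_ul[i] = clamp(lsd_ul[i] + gamma * (alpha - target_acc),
                            lsd_min, lsd_max);
      }
    }

    if (upd_p_l) {
      for (int i = 0; i < q_p; ++i) {
        double delta = std::exp(lsd_pl[i]) * norm_rand();
        double pnew = p_l[i] + delta;
        double dprior = -0.5 * Pinv[0] * (pnew * pnew - p_l[i] * p_l[i])
          - delta * Pinv[1] * p_t[i];
        const std::vector<int> &recs = rec_pe[i];
        double dll = dprior;
        for (size_t k = 0; k < recs.size(); ++k) {
          int r = recs[k];
          double nl = mbn_log_pmf_logit(y[r], t[r], lgt[r] + delta, logtheta, lch);
          prop_ll[r] = nl;
          dll += nl - ll[r];
        }
        double alpha = dll >= 0.0 ? 1.0 : std::exp(dll);
        if (unif_rand() < alpha) {
          p_l[i] = pnew;
          for (size_t k = 0; k < recs.size(); ++k) {
            int r = recs[k];
            lgt[r] += delta;
            ll[r] = prop_ll[r];
          }
          if (!adapting) acc_pl += 1;
        }
        if (!adapting) try_pl += 1;
        if (adapting)
          lsd_pl[i] = clamp(lsd_pl[i] + gamma * (alpha - target_acc),
                            lsd_min, lsd_max);
      }
    }

    if (upd_lam && n_g1) {
      for (int g = 0; g < n_g1; ++g) {
        if (rec_g1[g].empty()) continue;
        double delta = std::exp(lsd_lam[g]) * norm_rand();
        double dll = delta_loglik(rec_g1[g], 0, delta, 1.0);
        double alpha = dll >= 0.0 ? 1.0 : std::exp(dll);
        if (unif_rand() < alpha) {
          lam1[n_g1 == 9 ? g : 0] += delta;
          apply_shift(rec_g1[g], 0, delta, 1.0);
          if (!adapting) acc_lam += 1;
        }
        if (!adapting) try_lam += 1;
        if (adapting)
          lsd_lam[g] = clamp(lsd_lam[g] + gamma * (alpha - target_acc),
                             lsd_min, lsd_max);
      }
    }
    if (upd_lam && n_g2) {
      for (int g = 0; g < n_g2; ++g) {
        if (rec_g2[g].empty()) continue;
        double delta = std::exp(lsd_lam[n_g1 + g]) * norm_rand();
        double dll = delta_loglik(rec_g2[g], 0, delta, 2.0);
        double alpha = dll >= 0.0 ? 1.0 : std::exp(dll);
        if (unif_rand() < alpha) {
          lam2[n_g2 == 9 ? g : 0] += delta;
          apply_shift(rec_g2[g], 0, delta, 2.0);
          if (!adapting) acc_lam += 1;
        }
        if (!adapting) try_lam += 1;
        if (adapting)
          lsd_lam[n_g1 + g] = clamp(lsd_lam[n_g1 + g] + gamma * (alpha - target_acc),
                                    lsd_min, lsd_max);
      }
    }

    // ================= variance components ==============================
    if (upd_G) {
      // scale matrix U' A^{-1} U with a tiny ridge for numerical stability
      double S[3] = { 1e-12, 0.0, 1e-12 };
      for (int j = 0; j < q_u; ++j)
        for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
          int i = Ai[k];
          S[0] += Ax[k] * u_l[i] * u_l[j];
          S[1] += Ax[k] * u_l[i] * u_t[j];
          S[2] += Ax[k] * u_t[i] * u_t[j];
        }
      double df = (double) q_u - 3.0;
      if (df <= 1.0) stop("pedigree too small to update G (need >= 5 individuals)");
      bool ok = false;
      double cand[3];
      for (int tr = 0; tr < max_tries && !ok; ++tr) {
        if (!riwish2(df, S, cand)) continue;
        if (cand[0] > var_lo && cand[0] < var_hi &&
            cand[2] > var_lo && cand[2] < var_hi &&
            cand[0] * cand[2] - cand[1] * cand[1] > 0.0) ok = true;
      }
      if (!ok) stop("could not draw G within prior bounds after %d tries; widen the bounds", max_tries);
      G[0] = cand[0]; G[1] = cand[1]; G[2] = cand[2];
      inv2(G, Ginv);
    }

    if (upd_P) {
      double S[3] = { 1e-12, 0.0, 1e-12 };
      for (int i = 0; i < q_p; ++i) {
        S[0] += p_l[i] * p_l[i];
        S[1] += p_l[i] * p_t[i];
        S[2] += p_t[i] * p_t[i];
      }
      double df = (double) q_p - 3.0;
      if (df <= 1.0) stop("too few sows to update P (need >= 5)");
      bool ok = false;
      double cand[3];
      for (int tr = 0; tr < max_tries && !ok; ++tr) {
        if (!riwish2(df, S, cand)) continue;
        if (cand[0] > var_lo && cand[0] < var_hi &&
            cand[2] > var_lo && cand[2] < var_hi &&
            cand[0] * cand[2] - cand[1] * cand[1] > 0.0) ok = true;
      }
      if (!ok) stop("could not draw P within prior bounds after %d tries; widen the bounds", max_tries);
      P[0] = cand[0]; P[1] = cand[1]; P[2] = cand[2];
      inv2(P, Pinv);
    }

    if (upd_se) {
      double sse = 0.0;
      for (int r = 0; r < n; ++r) {
        double e = traw[r] - eta_t[r];
        sse += e * e;
      }
      double df = (double) n - 2.0;
      if (df <= 0.0) stop("too few records to update sigma2_et");
      bool ok = false;
      double cand = sig2e;
      for (int tr = 0; tr < max_tries && !ok; ++tr) {
        cand = sse / R::rchisq(df);
        if (cand > var_lo && cand < var_hi) ok = true;
      }
      if (!ok) stop("could not draw sigma2_et within prior bounds after %d tries; widen the bounds", max_tries);
      sig2e = cand;
    }

    // ================= dispersion parameter theta =======================
    if (upd_th) {
      double z = logtheta + std::exp(lsd_th) * norm_rand();
      double thnew = std::exp(z);
      double alpha = 0.0;
      bool inb = (thnew > th_lo && thnew <= th_hi);
      if (inb) {
        double dll = z - logtheta;       // Jacobian: flat prior on theta
        for (int r = 0; r < n; ++r) {
          double nl = mbn_log_pmf_logit(y[r], t[r], lgt[r], z, lch);
          prop_ll_theta[r] = nl;
          dll += nl - ll[r];
        }
        alpha = dll >= 0.0 ? 1.0 : std::exp(dll);
        if (unif_rand() < alpha) {
          logtheta = z;
          theta = thnew;
          std::swap(ll, prop_ll_theta);
          if (!adapting) acc_th += 1;
        }
      }
      if (!adapting) try_th += 1;
      if (adapting)
        lsd_th = clamp(lsd_th + gamma * (alpha - target_acc), lsd_min, lsd_max);
    }

    // ================= storage =========================================
    if (iter > burn_in && (iter - burn_in) % thin == 0 && kept < n_keep) {
      int c = 0;
      for (int j = 0; j < p; ++j) draws(kept, c++) = b_t[j];
      for (int j = 0; j < p; ++j) draws(kept, c++) = b_l[j];
      for (int g = 0; g < n_g1; ++g) draws(kept, c++) = lam1[n_g1 == 9 ? g : 0];
      for (int g = 0; g < n_g2; ++g) draws(kept, c++) = lam2[n_g2 == 9 ? g : 0];
      draws(kept, c++) = G[0]; draws(kept, c++) = G[1]; draws(kept, c++) = G[2];
      draws(kept, c++) = P[0]; draws(kept, c++) = P[1]; draws(kept, c++) = P[2];
      draws(kept, c++) = sig2e;
      draws(kept, c++) = theta;
      if (store_eff) {
        for (int i = 0; i < q_u; ++i) draws(kept, c++) = u_l[i];
        for (int i = 0; i < q_u; ++i) draws(kept, c++) = u_t[i];
        for (int i = 0; i < q_p; ++i) draws(kept, c++) = p_l[i];
        for (int i = 0; i < q_p; ++i) draws(kept, c++) = p_t[i];
      }
      for (int i = 0; i < q_u; ++i) {
        eff_mean(i, 0) += u_l[i]; eff_mean(i, 1) += u_t[i];
      }
      for (int i = 0; i < q_p; ++i) {
        eff_mean(q_u + i, 0) += p_l[i]; eff_mean(q_u + i, 1) += p_t[i];
      }
      if (store_ll)
        for (int r = 0; r < n; ++r) loglik(r, kept) = ll[r];
      ++kept;
    }

    if (iter % 512 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc = NumericVector::create(
    _["b_l"] = try_bl > 0 ? acc_bl / try_bl : NA_REAL,
    _["u_l"] = try_ul > 0 ? acc_ul / try_ul : NA_REAL,
    _["p_l"] = try_pl > 0 ? acc_pl / try_pl : NA_REAL,
    _["lambda"] = try_lam > 0 ? acc_lam / try_lam : NA_REAL,
    _["theta"] = try_th > 0 ? acc_th / try_th : NA_REAL);

  if (kept > 0)
    for (int i = 0; i < q_u + q_p; ++i) {
      eff_mean(i, 0) /= kept; eff_mean(i, 1) /= kept;
    }

  return List::create(
    _["draws"] = draws,
    _["loglik"] = loglik,
    _["acceptance"] = acc,
    _["n_g1"] = n_g1, _["n_g2"] = n_g2,
    _["effect_means"] = eff_mean);
}
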