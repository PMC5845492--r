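#include <Rcpp.h>
#include <numeric>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the joint outcome / exposure /
// measurement model. One sweep updates, in order:
//   (a) every latent true-exposure indicator from its exact Bernoulli full
//       conditional (data augmentation; skipped in naive mode),
//   (b) each regression coefficient by scalar random-walk Metropolis and the
//       cluster random intercepts u, v by per-cluster random walks,
//   (c) the random-intercept SDs sigma, nu by random walk on the log scale
//       (with Jacobian), respecting the uniform(0, sd_upper) prior,
//   (d) each sensitivity/specificity by a conjugate beta draw given the
//       augmented data.
// Proposal scales adapt by Robbins-Monro toward a 0.44 per-block acceptance
// rate during burn-in only, so the post-burn-in kernel is fixed.
//
// All randomness goes through R's RNG, so set.seed() in R makes runs
// bitwise reproducible.

static inline double softplus(double x) {
  return x > 0 ? x + log1p(std::exp(-x)) : log1p(std::exp(x));
}

static inline double clamp01(double p) {
  const double eps = 1e-12;
  return p < eps ? eps : (p > 1.0 - eps ? 1.0 - eps : p);
}

struct Block {
  double scale;
  long prop_kept = 0, acc_kept = 0;   // post-burn-in bookkeeping
  explicit Block(double s) : scale(s) {}
  void count(bool keep, long acc, long prop) {
    if (keep) { prop_kept += prop; acc_kept += acc; }
  }
};

// Robbins-Monro step on the log proposal scale
static inline void adapt_scale(double &scale, double acc_rate, int t, double target) {
  double step = 1.0 / std::sqrt((double)t + 1.0);
  if (step > 0.25) step = 0.25;
  scale *= std::exp(step * (acc_rate - target));
  if (scale < 1e-8) scale = 1e-8;
  if (scale > 50.0) scale = 50.0;
}

// [[Rcpp::export(name = ".run_mcmc_cpp")]]
List run_mcmc_cpp(NumericVector y, NumericVector r, IntegerVector cluster,
                  NumericMatrix Zy, NumericMatrix Zx,
                  IntegerVector x1, IntegerVector x2,
                  int mode,                 // 0 naive, 1 one_test, 2 two_test
                  List init, List priors, List ctrl) {
  const int n = y.size();
  const int N = max(cluster) + 1;           // cluster is 0-based contiguous
  const int py = Zy.ncol(), qx = Zx.ncol();
  const bool corrected = mode > 0;
  const bool two = mode == 2;

  // --- state ---------------------------------------------------------------
  double beta0 = init["beta0"], beta1 = init["beta1"];
  NumericVector betak = clone(as<NumericVector>(init["beta_k"]));
  NumericVector u = clone(as<NumericVector>(init["u"]));
  double sigma = init["sigma"];
  double gamma0 = 0, nu = 0.1, S1 = 0.5, C1 = 0.5, S2 = 0.5, C2 = 0.5;
  NumericVector gammak(qx), v(N);
  IntegerVector x(n);
  if (corrected) {
    gamma0 = init["gamma0"];
    gammak = clone(as<NumericVector>(init["gamma_k"]));
    v = clone(as<NumericVector>(init["v"]));
    nu = init["nu"];
    S1 = init["S1"]; C1 = init["C1"];
    if (two) { S2 = init["S2"]; C2 = init["C2"]; }
    x = clone(as<IntegerVector>(init["x_latent"]));
  } else {
    x = clone(x1);                          // naive: assessment taken as truth
  }

  // --- priors --------------------------------------------------------------
  const double beta_var = priors["beta_var"];
  const double gamma_var = corrected ? (double)priors["gamma_var"] : 1.0;
  const double sd_upper = priors["sd_upper"];
  double s1a = 1, s1b = 1, c1a = 1, c1b = 1, s2a = 1, s2b = 1, c2a = 1, c2b = 1;
  if (corrected) {
    NumericVector s1s = priors["s1"], c1s = priors["c1"];
    s1a = s1s[0]; s1b = s1s[1]; c1a = c1s[0]; c1b = c1s[1];
    if (two) {
      NumericVector s2s = priors["s2"], c2s = priors["c2"];
      s2a = s2s[0]; s2b = s2s[1]; c2a = c2s[0]; c2b = c2s[1];
    }
  }

  // --- control -------------------------------------------------------------
  const int n_burn = ctrl["n_burn"], n_iter = ctrl["n_iter"], thin = ctrl["thin"];
  const bool adapt = ctrl["adapt"];
  const double target = ctrl["target_accept"];
  const bool monitor_ranef = ctrl["monitor_ranef"];
  NumericVector scales0 = ctrl["scales"];   // per-block initial scales

  // block layout: beta0, beta1, betak..., [gamma0, gammak...], u, v, logsigma, lognu
  const int nb_coef = 2 + py + (corrected ? 1 + qx : 0);
  const int ib_u = nb_coef, ib_v = nb_coef + 1, ib_s = nb_coef + 2, ib_n = nb_coef + 3;
  const int nblocks = nb_coef + 4;
  std::vector<Block> blk;
  for (int b = 0; b < nblocks; ++b)
    blk.emplace_back(scales0.size() == nblocks ? scales0[b] : scales0[0]);

  // --- cached quantities ---------------------------------------------------
  NumericVector eta_y(n), lam(n), eta_x(n), sp(n);
  std::vector<double> Sy(N, 0.0);           // per-cluster sum of y (constant)
  for (int i = 0; i < n; ++i) Sy[cluster[i]] += y[i];
  double sum_y = std::accumulate(Sy.begin(), Sy.end(), 0.0);

  auto refresh_eta_y = [&]() {
    for (int i = 0; i < n; ++i) {
      double e = beta0 + u[cluster[i]] + beta1 * x[i];
      for (int k = 0; k < py; ++k) e += Zy(i, k) * betak[k];
      eta_y[i] = e; lam[i] = r[i] * std::exp(e);
    }
  };
  auto refresh_eta_x = [&]() {
    for (int i = 0; i < n; ++i) {
      double e = gamma0 + v[cluster[i]];
      for (int k = 0; k < qx; ++k) e += Zx(i, k) * gammak[k];
      eta_x[i] = e; sp[i] = softplus(e);
    }
  };
  refresh_eta_y();
  if (corrected) refresh_eta_x();

  for (int i = 0; i < n; ++i)
    if (!R_finite(lam[i]))
      stop("non-finite Poisson rate at initialization (subject %d)", i + 1);

  // --- output --------------------------------------------------------------
  int nmon = 2 + py + (corrected ? 1 + qx + (two ? 4 : 2) + 2 : 1);
  if (monitor_ranef) nmon += corrected ? 2 * N : N;
  const int n_keep = n_iter / thin;
  NumericMatrix draws(n_keep, nmon);
  NumericVector xbar(n);                    // posterior P(x=1) per subject
  int kept = 0;

  NumericVector scratch(n);
  std::vector<double> Slam(N), Sll(N), eps(N);

  RNGScope scope;
  const int total = n_burn + n_iter;
  for (int t = 0; t < total; ++t) {
    const bool burning = t < n_burn;
    const bool keep_stats = !burning;

    // ---- (a) latent exposure ----------------------------------------------
    if (corrected) {
      const double eb1 = std::exp(beta1);
      const double l1_1 = std::log(S1 / (1.0 - C1)), l1_0 = std::log((1.0 - S1) / C1);
      const double l2_1 = two ? std::log(S2 / (1.0 - C2)) : 0.0;
      const double l2_0 = two ? std::log((1.0 - S2) / C2) : 0.0;
      for (int i = 0; i < n; ++i) {
        double lam0 = x[i] ? lam[i] / eb1 : lam[i];
        double lo = eta_x[i] + y[i] * beta1 - lam0 * (eb1 - 1.0);
        lo += x1[i] ? l1_1 : l1_0;
        if (two) lo += x2[i] ? l2_1 : l2_0;
        int xn = unif_rand() < 1.0 / (1.0 + std::exp(-lo)) ? 1 : 0;
        if (xn != x[i]) {
          eta_y[i] += beta1 * (xn - x[i]);
          lam[i] = xn ? lam[i] * eb1 : lam[i] / eb1;
          x[i] = xn;
        }
      }
    }

    // ---- (b) outcome coefficients -----------------------------------------
    // beta0 (intercept: scalar shift, no per-subject exp needed)
    {
      Block &B = blk[0];
      double e = B.scale * norm_rand();
      double sum_lam = 0; for (int i = 0; i < n; ++i) sum_lam += lam[i];
      double d = e * sum_y - (std::exp(e) - 1.0) * sum_lam
        - ((beta0 + e) * (beta0 + e) - beta0 * beta0) / (2.0 * beta_var);
      bool acc = R_finite(d) && std::log(unif_rand()) < d;
      if (!R_finite(d) && !burning) stop("non-finite log-posterior delta in block beta0");
      if (acc) {
        double f = std::exp(e);
        for (int i = 0; i < n; ++i) { eta_y[i] += e; lam[i] *= f; }
        beta0 += e;
      }
      B.count(keep_stats, acc, 1);
      if (burning && adapt) adapt_scale(B.scale, acc ? 1.0 : 0.0, t, target);
    }
    // beta1 (binary covariate x: shift only where x == 1)
    {
      Block &B = blk[1];
      double e = B.scale * norm_rand();
      double sy1 = 0, sl1 = 0;
      for (int i = 0; i < n; ++i) if (x[i]) { sy1 += y[i]; sl1 += lam[i]; }
      double d = e * sy1 - (std::exp(e) - 1.0) * sl1
        - ((beta1 + e) * (beta1 + e) - beta1 * beta1) / (2.0 * beta_var);
      bool acc = R_finite(d) && std::log(unif_rand()) < d;
      if (acc) {
        double f = std::exp(e);
        for (int i = 0; i < n; ++i) if (x[i]) { eta_y[i] += e; lam[i] *= f; }
        beta1 += e;
      }
      B.count(keep_stats, acc, 1);
      if (burning && adapt) adapt_scale(B.scale, acc ? 1.0 : 0.0, t, target);
    }
    // remaining outcome coefficients
    for (int k = 0; k < py; ++k) {
      Block &B = blk[2 + k];
      double e = B.scale * norm_rand();
      double d = 0;
      for (int i = 0; i < n; ++i) {
        double de = e * Zy(i, k);
        double f = std::exp(de);
        scratch[i] = f;
        d += y[i] * de - lam[i] * (f - 1.0);
      }
      d -= ((betak[k] + e) * (betak[k] + e) - betak[k] * betak[k]) / (2.0 * beta_var);
      bool acc = R_finite(d) && std::log(unif_rand()) < d;
      if (acc) {
        for (int i = 0; i < n; ++i) { eta_y[i] += e * Zy(i, k); lam[i] *= scratch[i]; }
        betak[k] += e;
      }
      B.count(keep_stats, acc, 1);
      if (burning && adapt) adapt_scale(B.scale, acc ? 1.0 : 0.0, t, target);
    }

    // ---- (b) exposure coefficients ----------------------------------------
    if (corrected) {
      // gamma0
      {
        Block &B = blk[2 + py];
        double e = B.scale * norm_rand();
        double d = 0;
        for (int i = 0; i < n; ++i) {
          double spn = softplus(eta_x[i] + e);
          scratch[i] = spn;
          d += x[i] * e - (spn - sp[i]);
        }
        d -= ((gamma0 + e) * (gamma0 + e) - gamma0 * gamma0) / (2.0 * gamma_var);
        bool acc = R_finite(d) && std::log(unif_rand()) < d;
        if (acc) {
          for (int i = 0; i < n; ++i) { eta_x[i] += e; sp[i] = scratch[i]; }
          gamma0 += e;
        }
        B.count(keep_stats, acc, 1);
        if (burning && adapt) adapt_scale(B.scale, acc ? 1.0 : 0.0, t, target);
      }
      for (int k = 0; k < qx; ++k) {
        Block &B = blk[3 + py + k];
        double e = B.scale * norm_rand();
        double d = 0;
        for (int i = 0; i < n; ++i) {
          double de = e * Zx(i, k);
          double spn = softplus(eta_x[i] + de);
          scratch[i] = spn;
          d += x[i] * de - (spn - sp[i]);
        }
        d -= ((gammak[k] + e) * (gammak[k] + e) - gammak[k] * gammak[k]) / (2.0 * gamma_var);
        bool acc = R_finite(d) && std::log(unif_rand()) < d;
        if (acc) {
          for (int i = 0; i < n; ++i) { eta_x[i] += e * Zx(i, k); sp[i] = scratch[i]; }
          gammak[k] += e;
        }
        B.count(keep_stats, acc, 1);
        if (burning && adapt) adapt_scale(B.scale, acc ? 1.0 : 0.0, t, target);
      }
    }

    // ---- (b) outcome random intercepts u ----------------------------------
    {
      Block &B = blk[ib_u];
      for (int j = 0; j < N; ++j) { eps[j] = B.scale * norm_rand(); Slam[j] = 0; }
      for (int i = 0; i < n; ++i) Slam[cluster[i]] += lam[i];
      long acc_n = 0;
      for (int j = 0; j < N; ++j) {
        double d = eps[j] * Sy[j] - (std::exp(eps[j]) - 1.0) * Slam[j]
          - ((u[j] + eps[j]) * (u[j] + eps[j]) - u[j] * u[j]) / (2.0 * sigma * sigma);
        if (R_finite(d) && std::log(unif_rand()) < d) { u[j] += eps[j]; ++acc_n; }
        else eps[j] = 0.0;
      }
      if (acc_n)
        for (int i = 0; i < n; ++i) {
          double e = eps[cluster[i]];
          if (e != 0.0) { eta_y[i] += e; lam[i] *= std::exp(e); }
        }
      B.count(keep_stats, acc_n, N);
      if (burning && adapt) adapt_scale(B.scale, (double)acc_n / N, t, target);
    }

    // ---- (b) exposure random intercepts v ---------------------------------
    if (corrected) {
      Block &B = blk[ib_v];
      for (int j = 0; j < N; ++j) { eps[j] = B.scale * norm_rand(); Sll[j] = 0; }
      for (int i = 0; i < n; ++i) {
        double e = eps[cluster[i]];
        double spn = softplus(eta_x[i] + e);
        scratch[i] = spn;
        Sll[cluster[i]] += x[i] * e - (spn - sp[i]);
      }
      long acc_n = 0;
      for (int j = 0; j < N; ++j) {
        double d = Sll[j]
          - ((v[j] + eps[j]) * (v[j] + eps[j]) - v[j] * v[j]) / (2.0 * nu * nu);
        if (R_finite(d) && std::log(unif_rand()) < d) { v[j] += eps[j]; ++acc_n; }
        else eps[j] = 0.0;
      }
      if (acc_n)
        for (int i = 0; i < n; ++i) {
          double e = eps[cluster[i]];
          if (e != 0.0) { eta_x[i] += e; sp[i] = scratch[i]; }
        }
      B.count(keep_stats, acc_n, N);
      if (burning && adapt) adapt_scale(B.scale, (double)acc_n / N, t, target);
    }

    // ---- (c) random-intercept SDs (log-scale random walk + Jacobian) ------
    {
      Block &B = blk[ib_s];
      double e = B.scale * norm_rand();
      double sn = sigma * std::exp(e);
      bool acc = false;
      if (sn < sd_upper) {              // uniform(0, sd_upper) prior support
        double su2 = 0; for (int j = 0; j < N; ++j) su2 += u[j] * u[j];
        double d = -N * std::log(sn / sigma)
          - su2 / 2.0 * (1.0 / (sn * sn) - 1.0 / (sigma * sigma)) + e;
        acc = R_finite(d) && std::log(unif_rand()) < d;
        if (acc) sigma = sn;
      }
      B.count(keep_stats, acc, 1);
      if (burning && adapt) adapt_scale(B.scale, acc ? 1.0 : 0.0, t, target);
    }
    if (corrected) {
      Block &B = blk[ib_n];
      double e = B.scale * norm_rand();
      double nn = nu * std::exp(e);
      bool acc = false;
      if (nn < sd_upper) {
        double sv2 = 0; for (int j = 0; j < N; ++j) sv2 += v[j] * v[j];
        double d = -N * std::log(nn / nu)
          - sv2 / 2.0 * (1.0 / (nn * nn) - 1.0 / (nu * nu)) + e;
        acc = R_finite(d) && std::log(unif_rand()) < d;
        if (acc) nu = nn;
      }
      B.count(keep_stats, acc, 1);
      if (burning && adapt) adapt_scale(B.scale, acc ? 1.0 : 0.0, t, target);
    }

    // ---- (d) sensitivities/specificities: conjugate beta draws ------------
    if (corrected) {
      long n11 = 0, n10 = 0, n01 = 0, n00 = 0;
      for (int i = 0; i < n; ++i) {
        if (x[i]) { if (x1[i]) ++n11; else ++n10; }
        else      { if (x1[i]) ++n01; else ++n00; }
      }
      S1 = clamp01(R::rbeta(s1a + n11, s1b + n10));
      C1 = clamp01(R::rbeta(c1a + n00, c1b + n01));
      if (two) {
        long m11 = 0, m10 = 0, m01 = 0, m00 = 0;
        for (int i = 0; i < n; ++i) {
          if (x[i]) { if (x2[i]) ++m11; else ++m10; }
          else      { if (x2[i]) ++m01; else ++m00; }
        }
        S2 = clamp01(R::rbeta(s2a + m11, s2b + m10));
        C2 = clamp01(R::rbeta(c2a + m00, c2b + m01));
      }
    }

    // ---- store -------------------------------------------------------------
    if (!burning && (t - n_burn) % thin == 0 && kept < n_keep) {
      {
        int c = 0;
        draws(kept, c++) = beta0;
        draws(kept, c++) = beta1;
        for (int k = 0; k < py; ++k) draws(kept, c++) = betak[k];
        if (corrected) {
          draws(kept, c++) = gamma0;
          for (int k = 0; k < qx; ++k) draws(kept, c++) = gammak[k];
          draws(kept, c++) = S1;
          draws(kept, c++) = C1;
          if (two) { draws(kept, c++) = S2; draws(kept, c++) = C2; }
        }
        draws(kept, c++) = sigma;
        if (corrected) draws(kept, c++) = nu;
        if (monitor_ranef) {
          for (int j = 0; j < N; ++j) draws(kept, c++) = u[j];
          if (corrected) for (int j = 0; j < N; ++j) draws(kept, c++) = v[j];
        }
        if (corrected) for (int i = 0; i < n; ++i) xbar[i] += x[i];
        ++kept;
      }
    }
  }
  if (kept) for (int i = 0; i < n; ++i) xbar[i] /= kept;

  NumericVector acc_rates(nblocks), fin_scales(nblocks);
  for (int b = 0; b < nblocks; ++b) {
    acc_rates[b] = blk[b].prop_kept ? (double)blk[b].acc_kept / blk[b].prop_kept : NA_REAL;
    fin_scales[b] = blk[b].scale;
  }

  List fin = List::create(
    _["beta0"] = beta0, _["beta1"] = beta1, _["beta_k"] = betak,
    _["u"] = u, _["sigma"] = sigma);
  if (corrected) {
    fin["gamma0"] = gamma0; fin["gamma_k"] = gammak; fin["v"] = v; fin["nu"] = nu;
    fin["S1"] = S1; fin["C1"] = C1;
    if (two) { fin["S2"] = S2; fin["C2"] = C2; }
    fin["x_latent"] = x;
  }

  return List::create(
    _["draws"] = draws, _["accept"] = acc_rates, _["scales"] = fin_scales,
    _["final"] = fin, _["x_prob"] = xbar);
}
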