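// Adaptive random-walk Metropolis machinery for the linked one-compartment
// dose-to-mother model. Parameters are sampled on the natural-log scale in
// the fixed order (ln k_mm, ln V_m, ln CL_mb, ln CL_bo).
#include <Rcpp.h>
using namespace Rcpp;


// Model prediction for one observation.
// role: 0 = mother, 1 = infant. Vb is the infant body-water volume (kg).
static inline double predict_one(double dose, double k_mm, double V_m,
                                 double CL_mb, double CL_bo, double Vb,
                                 double t, int role) {
  if (role == 0) {
    return dose * 1000.0 / V_m * std::exp(-k_mm * t);
  }
  double k_bb = CL_bo / Vb;
  double scale = dose * 1000.0 * CL_mb / (V_m * Vb);
  double d = k_bb - k_mm;
  if (std::fabs(d) < 1e-8) {
    return scale * t * std::exp(-k_mm * t);
  }
  return scale * (std::exp(-k_mm * t) - std::exp(-k_bb * t)) / d;
}

// Log-likelihood of one pair's observations under the residual model.
// combined: var = f^2 s1^2 + s2^2 ; additive: var = s1^2.
static double loglik_pair(const NumericVector& t, const NumericVector& y,
                          const IntegerVector& role, double dose, double Vb,
                          double s1, double s2, bool combined,
                          const double* theta, const double* lo,
                          const double* hi) {
  for (int j = 0; j < 4; ++j) {
    if (!std::isfinite(theta[j]) || theta[j] < lo[j] || theta[j] > hi[j])
      return R_NegInf;
  }
  double k_mm = std::exp(theta[0]), V_m = std::exp(theta[1]);
  double CL_mb = std::exp(theta[2]), CL_bo = std::exp(theta[3]);
  double ll = 0.0;
  int n = t.size();
  for (int i = 0; i < n; ++i) {
    double f = predict_one(dose, k_mm, V_m, CL_mb, CL_bo, Vb, t[i], role[i]);
    double var = combined ? (f * f * s1 * s1 + s2 * s2) : (s1 * s1);
    if (!(var > 0.0) || !std::isfinite(var)) return R_NegInf;
    double r = y[i] - f;
    ll += -0.5 * (std::log(2.0 * M_PI * var) + r * r / var);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_loglik(NumericVector theta, NumericVector t, NumericVector y,
                  IntegerVector role, double dose, double Vb,
                  double sigma1, double sigma2, bool combined,
                  NumericVector lower, NumericVector upper) {
  return loglik_pair(t, y, role, dose, Vb, sigma1, sigma2, combined,
                     REAL(theta), REAL(lower), REAL(upper));
}

static inline double dnorm_log(double x, double mu, double sd) {
  double r = (x - mu) / sd;
  return -0.5 * (std::log(2.0 * M_PI) + r * r) - std::log(sd);
}

// Cholesky factor (lower) of a 4x4 SPD matrix; returns false on failure.
static bool chol4(const double S[4][4], double L[4][4]) {
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) L[i][j] = 0.0;
  for (int i = 0; i < 4; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = S[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      if (i == j) {
        if (s <= 0.0) return false;
        L[i][i] = std::sqrt(s);
      } else {
        L[i][j] = s / L[j][j];
      }
    }
  }
  return true;
}

// Adaptive-covariance random-walk Metropolis for a single mother-infant
// pair with independent normal priors on the four log parameters.
// init: n_chains x 4 starting values. Returns kept draws per chain and the
// warmup acceptance rate. Uses R's RNG (reproducible under set.seed()).
// [[Rcpp::export]]
List cpp_fit_pair(NumericVector t, NumericVector y, IntegerVector role,
                  double dose, double Vb,
                  NumericVector prior_mean, NumericVector prior_sd,
                  double sigma1, double sigma2, bool combined,
                  NumericMatrix init, int n_warmup, int n_keep,
                  NumericVector lower, NumericVector upper) {
  int n_chains = init.nrow();
  const double* lo = REAL(lower);
  const double* hi = REAL(upper);
  RNGScope scope;
  NumericMatrix draws(n_chains * n_keep, 4);
  IntegerVector chain_id(n_chains * n_keep);
  NumericVector accept_rate(n_chains);

  for (int c = 0; c < n_chains; ++c) {
    double theta[4];
    for (int j = 0; j < 4; ++j) theta[j] = init(c, j);
    double lp = loglik_pair(t, y, role, dose, Vb, sigma1, sigma2, combined,
                            theta, lo, hi);
    for (int j = 0; j < 4; ++j) lp += dnorm_log(theta[j], prior_mean[j], prior_sd[j]);

    // proposal state: global log-scale + running moments for covariance
    double log_s = std::log(0.3);
    double mean[4], cov[4][4], L[4][4];
    for (int j = 0; j < 4; ++j) {
      mean[j] = theta[j];
      for (int k = 0; k < 4; ++k) cov[j][k] = (j == k) ? 1.0 : 0.0;
    }
    // start from prior-informed diagonal scales (capped for diffuse priors)
    double S[4][4];
    for (int j = 0; j < 4; ++j)
      for (int k = 0; k < 4; ++k)
        S[j][k] = (j == k) ? std::pow(std::min(prior_sd[j], 1.0), 2) : 0.0;
    chol4(S, L);

    long n_acc = 0;
    int total = n_warmup + n_keep;
    int adapt_count = 0;
    for (int it = 0; it < total; ++it) {
      double z[4], prop[4];
      for (int j = 0; j < 4; ++j) z[j] = norm_rand();
      double s = std::exp(log_s);
      for (int j = 0; j < 4; ++j) {
        double step = 0.0;
        for (int k = 0; k <= j; ++k) step += L[j][k] * z[k];
        prop[j] = theta[j] + s * step;
      }
      double lp_prop = loglik_pair(t, y, role, dose, Vb, sigma1, sigma2,
                                   combined, prop, lo, hi);
      if (std::isfinite(lp_prop)) {
        for (int j = 0; j < 4; ++j)
          lp_prop += dnorm_log(prop[j], prior_mean[j], prior_sd[j]);
      }
      double alpha = 0.0;
      if (std::isfinite(lp_prop)) {
        alpha = std::exp(std::min(0.0, lp_prop - lp));
        if (unif_rand() < alpha) {
          for (int j = 0; j < 4; ++j) theta[j] = prop[j];
          lp = lp_prop;
          ++n_acc;
        }
      }

      if (it < n_warmup) {
        // Robbins-Monro scale adaptation toward 0.3 acceptance, plus
        // running covariance adaptation (Haario-style) after burn-in.
        ++adapt_count;
        double gam = 1.0 / std::pow((double)adapt_count, 0.6);
        log_s += gam * (alpha - 0.3);
        for (int j = 0; j < 4; ++j) {
          double dj = theta[j] - mean[j];
          mean[j] += gam * dj;
          for (int k = 0; k <= j; ++k) {
            double dk = theta[k] - mean[k];
            cov[j][k] += gam * (dj * dk - cov[j][k]);
            cov[k][j] = cov[j][k];
          }
        }
        if (adapt_count >= 100 && adapt_count % 25 == 0) {
          double Snew[4][4];
          for (int j = 0; j < 4; ++j)
            for (int k = 0; k < 4; ++k)
              Snew[j][k] = cov[j][k] + ((j == k) ? 1e-6 : 0.0);
          double Ltry[4][4];
          if (chol4(Snew, Ltry)) {
            for (int j = 0; j < 4; ++j)
              for (int k = 0; k < 4; ++k) L[j][k] = Ltry[j][k];
          }
        }
      } else {
        int row = c * n_keep + (it - n_warmup);
        for (int j = 0; j < 4; ++j) draws(row, j) = theta[j];
        chain_id[row] = c + 1;
      }
    }
    accept_rate[c] = (double)n_acc / (double)total;
  }
  return List::create(_["draws"] = draws, _["chain"] = chain_id,
                      _["accept_rate"] = accept_rate);
}

// One Metropolis sweep over every pair's individual log-parameters given
// the current population means mu (n x 4), BSV SDs omega (4), and residual
// sigmas per pair. Observations are passed flattened with [start, end)
// offsets per pair. Proposals use a per-pair lower-triangular factor Lmat
// (n x 16, row-major 4x4) scaled by scale[i]; pass the identity to recover
// isotropic steps. eta is modified in place semantics via returned copy.
// [[Rcpp::export]]
List cpp_update_etas(NumericMatrix eta, NumericMatrix mu, NumericVector omega,
                     NumericVector t, NumericVector y, IntegerVector role,
                     IntegerVector start, IntegerVector len,
                     NumericVector dose, NumericVector Vb,
                     NumericVector sigma1, NumericVector sigma2, bool combined,
                     NumericVector scale, NumericVector loglik_cur,
                     NumericVector lower, NumericVector upper,
                     NumericMatrix Lmat) {
  int n = eta.nrow();
  const double* lo = REAL(lower);
  const double* hi = REAL(upper);
  RNGScope scope;
  NumericMatrix eta_new(clone(eta));
  NumericVector ll(clone(loglik_cur));
  IntegerVector accepted(n);
  for (int i = 0; i < n; ++i) {
    NumericVector ti(t.begin() + start[i], t.begin() + start[i] + len[i]);
    NumericVector yi(y.begin() + start[i], y.begin() + start[i] + len[i]);
    IntegerVector ri(role.begin() + start[i], role.begin() + start[i] + len[i]);
    double cur[4], prop[4], z[4];
    for (int j = 0; j < 4; ++j) cur[j] = eta_new(i, j);
    for (int j = 0; j < 4; ++j) z[j] = norm_rand();
    for (int j = 0; j < 4; ++j) {
      double step = 0.0;
      for (int k = 0; k <= j; ++k) step += Lmat(i, 4 * j + k) * z[k];
      prop[j] = cur[j] + scale[i] * step;
    }
    double ll_prop = loglik_pair(ti, yi, ri, dose[i], Vb[i],
                                 sigma1[i], sigma2[i], combined, prop, lo, hi);
    if (std::isfinite(ll_prop)) {
      double lp_cur = ll[i], lp_prop = ll_prop;
      for (int j = 0; j < 4; ++j) {
        lp_cur += dnorm_log(cur[j], mu(i, j), omega[j]);
        lp_prop += dnorm_log(prop[j], mu(i, j), omega[j]);
      }
      if (std::log(unif_rand()) < lp_prop - lp_cur) {
        for (int j = 0; j < 4; ++j) eta_new(i, j) = prop[j];
        ll[i] = ll_prop;
        accepted[i] = 1;
      }
    }
  }
  return List::create(_["eta"] = eta_new, _["loglik"] = ll,
                      _["accepted"] = accepted);
}

// Log-likelihood of every pair at the supplied etas (used after residual
// sigma updates in the population sampler).
// [[Rcpp::export]]
NumericVector cpp_loglik_all(NumericMatrix eta,
                             NumericVector t, NumericVector y,
                             IntegerVector role, IntegerVector start,
                             IntegerVector len, NumericVector dose,
                             NumericVector Vb, NumericVector sigma1,
                             NumericVector sigma2, bool combined,
                             NumericVector lower, NumericVector upper) {
  int n = eta.nrow();
  const double* lo = REAL(lower);
  const double* hi = REAL(upper);
  NumericVector ll(n);
  for (int i = 0; i < n; ++i) {
    NumericVector ti(t.begin() + start[i], t.begin() + start[i] + len[i]);
    NumericVector yi(y.begin() + start[i], y.begin() + start[i] + len[i]);
    IntegerVector ri(role.begin() + start[i], role.begin() + start[i] + len[i]);
    double theta[4];
    for (int j = 0; j < 4; ++j) theta[j] = eta(i, j);
    ll[i] = loglik_pair(ti, yi, ri, dose[i], Vb[i], sigma1[i], sigma2[i],
                        combined, theta, lo, hi);
  }
  return ll;
}
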