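#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Inner machinery for the mixture-model marker solvers.  Both the EM and the
// Gibbs sampler sweep markers in fixed ascending order with an immediately
// updated running residual (Gauss-Seidel style).
//
// Two storage layouts are supported:
//  * a dense double design matrix Z (any real covariates), and
//  * a compact dosage layout: one byte per genotype (0/1/2, 3 = missing)
//    plus per-marker frequency p_i and scale s_i, so that
//    Z_ij = (x_ij - 2 p_i) s_i and Z_i'e = s_i (sum_j x_ij e_j - 2 p_i T0)
//    with T0 = sum(e) maintained incrementally.  The residual vector stays
//    cache-resident and each sweep streams only one byte per genotype, which
//    is what makes whole-panel sampling affordable on one core.

static inline double dot_col(const double* z, const double* e, int n) {
  double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
  int j = 0;
  for (; j + 4 <= n; j += 4) {
    s0 += z[j] * e[j];
    s1 += z[j + 1] * e[j + 1];
    s2 += z[j + 2] * e[j + 2];
    s3 += z[j + 3] * e[j + 3];
  }
  for (; j < n; ++j) s0 += z[j] * e[j];
  return (s0 + s1) + (s2 + s3);
}

static inline void axpy_col(const double* z, double a, double* e, int n) {
  for (int j = 0; j < n; ++j) e[j] += a * z[j];
}

static inline double dot_x(const unsigned char* x, const double* e, int n) {
  double s0 = 0.0, s1 = 0.0, s2 = 0.0, s3 = 0.0;
  int j = 0;
  for (; j + 4 <= n; j += 4) {
    s0 += (double)x[j] * e[j];
    s1 += (double)x[j + 1] * e[j + 1];
    s2 += (double)x[j + 2] * e[j + 2];
    s3 += (double)x[j + 3] * e[j + 3];
  }
  for (; j < n; ++j) s0 += (double)x[j] * e[j];
  return (s0 + s1) + (s2 + s3);
}

// Marginal log-likelihood of the scalar statistic r_i = Z_i'y(dagger) under
// mixture component k: r_i ~ N(0, zz^2 * sigma_k2 + zz * sigma_e2 + w_i),
// where w_i = Z_i' PEV Z_i carries the estimation error of all other markers.
static inline void component_loglik4(double r, double zz, double w,
                                     const double* sigma_k2, double sigma_e2,
                                     double* ll) {
  double r2 = r * r;
  for (int k = 0; k < 4; ++k) {
    double v = zz * zz * sigma_k2[k] + zz * sigma_e2 + w;
    ll[k] = -0.5 * (std::log(v) + r2 / v);
  }
}

// Uniform access to the two layouts.
struct Design {
  const double* Z;           // dense layout (column-major), or NULL
  const unsigned char* X;    // compact layout, or NULL
  const double* p;           // allele frequencies (compact layout)
  const double* s;           // scales (compact layout)
  const int* clean;          // 1 if column has no missing entries
  int n, m;
  std::vector<double> colsum;   // per-column sum of Z entries
  std::vector<double> sumx;     // per-column sum of non-missing dosages

  void init(const NumericMatrix& Zm, const RawMatrix& Xm,
            const NumericVector& pv, const NumericVector& sv,
            const IntegerVector& cleanv) {
    if (Xm.nrow() > 0) {
      X = (const unsigned char*)Xm.begin();
      Z = nullptr;
      p = pv.begin();
      s = sv.begin();
      clean = cleanv.begin();
      n = Xm.nrow();
      m = Xm.ncol();
    } else {
      Z = Zm.begin();
      X = nullptr;
      p = s = nullptr;
      clean = nullptr;
      n = Zm.nrow();
      m = Zm.ncol();
    }
    colsum.assign(m, 0.0);
    sumx.assign(m, 0.0);
    for (int i = 0; i < m; ++i) {
      if (X) {
        const unsigned char* xi = X + (size_t)i * n;
        double sx = 0.0;
        int nobs = 0;
        for (int j = 0; j < n; ++j) {
          if (xi[j] != 3) { sx += xi[j]; ++nobs; }
        }
        sumx[i] = sx;
        colsum[i] = s[i] * (sx - 2.0 * p[i] * nobs);
      } else {
        const double* zi = Z + (size_t)i * n;
        double c = 0.0;
        for (int j = 0; j < n; ++j) c += zi[j];
        colsum[i] = c;
      }
    }
  }

  // Z_i' e, given the running total T0 = sum(e)
  inline double cross(int i, const double* e, double T0) const {
    if (X) {
      const unsigned char* xi = X + (size_t)i * n;
      if (clean[i]) return s[i] * (dot_x(xi, e, n) - 2.0 * p[i] * T0);
      double t1 = 0.0, t0 = 0.0;
      for (int j = 0; j < n; ++j) {
        if (xi[j] != 3) { t1 += (double)xi[j] * e[j]; t0 += e[j]; }
      }
      return s[i] * (t1 - 2.0 * p[i] * t0);
    }
    return dot_col(Z + (size_t)i * n, e, n);
  }

  // e += a * Z_i ; returns the change in sum(e), which is a * colsum[i]
  inline double update(int i, double a, double* e) const {
    if (X) {
      const unsigned char* xi = X + (size_t)i * n;
      const double c1 = a * s[i];
      const double c0 = -2.0 * p[i] * a * s[i];
      if (clean[i]) {
        for (int j = 0; j < n; ++j) e[j] += c1 * (double)xi[j] + c0;
      } else {
        for (int j = 0; j < n; ++j) {
          if (xi[j] != 3) e[j] += c1 * (double)xi[j] + c0;
        }
      }
    } else {
      axpy_col(Z + (size_t)i * n, a, e, n);
    }
    return a * colsum[i];
  }

  // e = y - mu - Z g, refreshed from scratch
  void rebuild(const NumericVector& y, double mu, const std::vector<double>& g,
               std::vector<double>& e) const {
    for (int j = 0; j < n; ++j) e[j] = y[j] - mu;
    for (int i = 0; i < m; ++i) {
      if (g[i] != 0.0) update(i, -g[i], e.data());
    }
  }
};

// [[Rcpp::export]]
List em_fit_cpp(NumericMatrix Z, RawMatrix Xraw, NumericVector freqs,
                NumericVector scales, IntegerVector clean_cols,
                NumericVector y, NumericVector diag_zz,
                NumericVector sigma_k2, NumericVector alpha,
                NumericVector w, double trace_pev, bool use_w, bool use_trace,
                bool update_sigma_e2,
                int estimator,      // 0 = mode, 1 = mean
                int spike_rule,     // 0 = zero at MAP-null, 1 = as-printed ridge
                double g_init, NumericVector pr_init, double sigma_e2_init,
                double gamma, int max_iter, int audit_every) {
  Design D;
  D.init(Z, Xraw, freqs, scales, clean_cols);
  const int n = D.n, m = D.m;
  std::vector<double> g(m, g_init), g_prev(m);
  NumericMatrix P(m, 4);
  double Pr[4], mu, sigma_e2 = sigma_e2_init;
  for (int k = 0; k < 4; ++k) Pr[k] = pr_init[k];

  mu = mean(y);
  std::vector<double> e(n);
  D.rebuild(y, mu, g, e);

  std::vector<double> traj_se2, traj_pr1, traj_ratio;
  traj_se2.reserve(256); traj_pr1.reserve(256); traj_ratio.reserve(256);
  const double tp = use_trace ? trace_pev : 0.0;
  bool converged = false, degenerate = false;
  double max_drift = 0.0;
  int iter = 0;
  double ll[4], lp[4], Pk[4];

  for (iter = 1; iter <= max_iter; ++iter) {
    g_prev = g;
    double colsumP[4] = {0, 0, 0, 0};
    double T0 = 0.0;
    for (int j = 0; j < n; ++j) T0 += e[j];

    for (int i = 0; i < m; ++i) {
      const double zz = diag_zz[i];
      const double wi = use_w ? w[i] : 0.0;
      const double r = D.cross(i, e.data(), T0) + zz * g[i];

      component_loglik4(r, zz, wi, sigma_k2.begin(), sigma_e2, ll);
      double lmax = -INFINITY;
      for (int k = 0; k < 4; ++k) {
        lp[k] = (Pr[k] > 0.0 ? std::log(Pr[k]) : -INFINITY) + ll[k];
        if (lp[k] > lmax) lmax = lp[k];
      }
      double psum = 0.0;
      for (int k = 0; k < 4; ++k) { Pk[k] = std::exp(lp[k] - lmax); psum += Pk[k]; }
      int kmap = 0;
      for (int k = 0; k < 4; ++k) {
        Pk[k] /= psum;
        P(i, k) = Pk[k];
        colsumP[k] += Pk[k];
        if (Pk[k] > Pk[kmap]) kmap = k;
      }

      double gnew;
      if (estimator == 1) {                       // posterior mean
        double sacc = 0.0;
        for (int k = 1; k < 4; ++k) sacc += Pk[k] / (zz + sigma_e2 / sigma_k2[k]);
        gnew = r * sacc;
      } else if (spike_rule == 0 && kmap == 0) {  // spike is the MAP component
        gnew = 0.0;
      } else {                                    // conditional ridge mode
        double den = zz;
        for (int k = 1; k < 4; ++k) den += Pk[k] * sigma_e2 / sigma_k2[k];
        gnew = r / den;
      }

      double delta = gnew - g[i];
      if (delta != 0.0) {
        T0 += D.update(i, -delta, e.data());
        g[i] = gnew;
      }
    }

    // mixing proportions: Dirichlet pseudo-counts added to soft counts
    double prden = 0.0;
    for (int k = 0; k < 4; ++k) prden += colsumP[k] + alpha[k];
    for (int k = 0; k < 4; ++k) Pr[k] = (colsumP[k] + alpha[k]) / prden;

    // error variance, then mean (the PEV trace enters only with the correction)
    if (update_sigma_e2) {
      double sse = 0.0;
      for (int j = 0; j < n; ++j) sse += e[j] * e[j];
      sigma_e2 = (sse + tp) / n;
    }
    double ebar = 0.0;
    for (int j = 0; j < n; ++j) ebar += e[j];
    ebar /= n;
    mu += ebar;
    for (int j = 0; j < n; ++j) e[j] -= ebar;

    // convergence on the relative squared change of the effect vector
    double num = 0.0, den = 0.0;
    for (int i = 0; i < m; ++i) {
      double d = g[i] - g_prev[i];
      num += d * d;
      den += g[i] * g[i];
    }
    double ratio = (den > 0.0) ? num / den : NA_REAL;
    traj_se2.push_back(sigma_e2);
    traj_pr1.push_back(Pr[0]);
    traj_ratio.push_back(ratio);
    if (den <= 0.0) {
      degenerate = true;            // all-zero effect vector: keep iterating
    } else if (ratio < gamma) {
      converged = true;
      break;
    }

    if (audit_every > 0 && iter % audit_every == 0) {
      // recompute the residual from scratch and measure accumulated drift
      std::vector<double> ref(n);
      D.rebuild(y, mu, g, ref);
      double drift = 0.0;
      for (int j = 0; j < n; ++j)
        drift = std::max(drift, std::fabs(ref[j] - e[j]));
      max_drift = std::max(max_drift, drift);
      e = ref;
    }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(
    _["g"] = NumericVector(g.begin(), g.end()), _["P"] = P,
    _["Pr"] = NumericVector::create(Pr[0], Pr[1], Pr[2], Pr[3]),
    _["sigma_e2"] = sigma_e2, _["mu"] = mu,
    _["residual"] = NumericVector(e.begin(), e.end()),
    _["iterations"] = iter, _["converged"] = converged,
    _["degenerate"] = degenerate, _["max_residual_drift"] = max_drift,
    _["trace_sigma_e2"] = NumericVector(traj_se2.begin(), traj_se2.end()),
    _["trace_pr1"] = NumericVector(traj_pr1.begin(), traj_pr1.end()),
    _["trace_ratio"] = NumericVector(traj_ratio.begin(), traj_ratio.end()));
}

// [[Rcpp::export]]
List gibbs_cpp(NumericMatrix Z, RawMatrix Xraw, NumericVector freqs,
               NumericVector scales, IntegerVector clean_cols,
               NumericVector y, NumericVector diag_zz,
               NumericVector sigma_k2, NumericVector alpha,
               int n_iter, int burn_in, int thin,
               NumericVector pr_init, double sigma_e2_init) {
  Design D;
  D.init(Z, Xraw, freqs, scales, clean_cols);
  const int n = D.n, m = D.m;
  std::vector<double> g(m, 0.0), Pr(4);
  for (int k = 0; k < 4; ++k) Pr[k] = pr_init[k];
  double sigma_e2 = sigma_e2_init;
  double mu = mean(y);
  std::vector<double> e(n);
  for (int j = 0; j < n; ++j) e[j] = y[j] - mu;

  std::vector<double> g_sum(m, 0.0);
  std::vector<double> occ(4 * (size_t)m, 0.0);  // component occupancy counts
  double pr_sum[4] = {0, 0, 0, 0};
  double se2_sum = 0.0, mu_sum = 0.0;
  int kept = 0;
  NumericMatrix trace(n_iter, 5);  // sigma_e2, Pr1..Pr4
  double ll[4], lp[4], pk[4];

  RNGScope scope;
  for (int it = 1; it <= n_iter; ++it) {
    int counts[4] = {0, 0, 0, 0};
    double T0 = 0.0;
    for (int j = 0; j < n; ++j) T0 += e[j];
    bool keep_draw = (it > burn_in) && ((it - burn_in) % thin == 0);

    for (int i = 0; i < m; ++i) {
      const double zz = diag_zz[i];
      double r = D.cross(i, e.data(), T0) + zz * g[i];

      component_loglik4(r, zz, 0.0, sigma_k2.begin(), sigma_e2, ll);
      double lmax = -INFINITY;
      for (int k = 0; k < 4; ++k) {
        lp[k] = (Pr[k] > 0.0 ? std::log(Pr[k]) : -INFINITY) + ll[k];
        if (lp[k] > lmax) lmax = lp[k];
      }
      double psum = 0.0;
      for (int k = 0; k < 4; ++k) { pk[k] = std::exp(lp[k] - lmax); psum += pk[k]; }
      double u = R::runif(0.0, psum);
      int k = 0;
      double cum = pk[0];
      while (k < 3 && u > cum) cum += pk[++k];
      counts[k]++;

      double gnew;
      if (k == 0) {
        gnew = 0.0;
      } else {
        double den = zz + sigma_e2 / sigma_k2[k];
        gnew = r / den + std::sqrt(sigma_e2 / den) * R::norm_rand();
      }
      if (!std::isfinite(gnew)) stop("non-finite sample at iteration %d", it);
      double delta = gnew - g[i];
      if (delta != 0.0) {
        T0 += D.update(i, -delta, e.data());
        g[i] = gnew;
      }
      if (keep_draw) occ[(size_t)i * 4 + k] += 1.0;
    }

    // Pr | counts ~ Dirichlet(alpha + counts)
    double gam[4], gsumv = 0.0;
    for (int k = 0; k < 4; ++k) {
      gam[k] = R::rgamma(alpha[k] + counts[k], 1.0);
      gsumv += gam[k];
    }
    for (int k = 0; k < 4; ++k) Pr[k] = gam[k] / gsumv;

    // mu | rest ~ N(mean(y - Zg), sigma_e2 / n)
    double ebar = 0.0;
    for (int j = 0; j < n; ++j) ebar += e[j];
    ebar /= n;
    double mu_new = mu + ebar + std::sqrt(sigma_e2 / n) * R::norm_rand();
    double shift = mu_new - mu;
    for (int j = 0; j < n; ++j) e[j] -= shift;
    mu = mu_new;

    // sigma_e2 | rest: scaled inverse chi-square with a flat prior
    double sse = 0.0;
    for (int j = 0; j < n; ++j) sse += e[j] * e[j];
    sigma_e2 = sse / R::rchisq((double)n - 2.0);
    if (!std::isfinite(sigma_e2) || sigma_e2 <= 0.0)
      stop("non-finite error variance at iteration %d", it);

    trace(it - 1, 0) = sigma_e2;
    for (int k = 0; k < 4; ++k) trace(it - 1, k + 1) = Pr[k];

    if (keep_draw) {
      kept++;
      for (int i = 0; i < m; ++i) g_sum[i] += g[i];
      for (int k = 0; k < 4; ++k) pr_sum[k] += Pr[k];
      se2_sum += sigma_e2;
      mu_sum += mu;
    }

    // periodic fresh residual so round-off cannot accumulate over the chain
    if (it % 500 == 0) {
      std::vector<double> ref(n);
      D.rebuild(y, mu, g, ref);
      e = ref;
    }
    if (it % 100 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector g_mean(m);
  NumericMatrix P_mean(m, 4);
  for (int i = 0; i < m; ++i) {
    g_mean[i] = g_sum[i] / kept;
    for (int k = 0; k < 4; ++k) P_mean(i, k) = occ[(size_t)i * 4 + k] / kept;
  }
  NumericVector pr_mean(4);
  for (int k = 0; k < 4; ++k) pr_mean[k] = pr_sum[k] / kept;

  return List::create(
    _["g_mean"] = g_mean, _["P_mean"] = P_mean, _["Pr_mean"] = pr_mean,
    _["sigma_e2_mean"] = se2_sum / kept, _["mu_mean"] = mu_sum / kept,
    _["samples_kept"] = kept, _["trace"] = trace);
}
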