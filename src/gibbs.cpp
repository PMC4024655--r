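#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// P(gamma_j = 1) = 1 / (1 + exp(log_q)), computed without overflow.
static inline double incl_prob_from_logq(double log_q) {
  if (log_q > 0.0) {
    double t = std::exp(-log_q);
    return t / (1.0 + t);
  }
  return 1.0 / (1.0 + std::exp(log_q));
}

static inline void check_variance(double v, const char* what) {
  if (!R_FINITE(v) || v > 1e12 || v < 1e-12)
    stop("Gibbs chain diverged: %s = %g out of [1e-12, 1e12]", what, v);
}

// Single-site Gibbs sampler over (gamma, a, w, sigma2_a, sigma2_e, mu) with
// maintained residuals e = y - mu[pop] - X a.
//
// Samples must be sorted so populations form contiguous row blocks (the hot
// loops run per block and vectorize).  `pop` holds the 0-based population
// (intercept group) of each sample; `task_of_pop` maps each population to the
// 0-based effect column it uses.  The multi-task model uses task_of_pop =
// 0..(c-1); the pooled model maps every population to task 0 so that one
// effect vector and one pair of variances is shared while intercepts stay
// population specific.
//
// [[Rcpp::export(name = ".gibbs_core")]]
List gibbs_core(const NumericMatrix& X,
                const NumericVector& y,
                const IntegerVector& pop,
                const int n_pop,
                const IntegerVector& task_of_pop,
                const int n_task,
                const NumericVector& v_a, const NumericVector& s2_a,
                const NumericVector& v_e, const NumericVector& s2_e,
                const int n_iter, const int burn_in, const int thin,
                const bool w_plus_one,
                const bool update_w, const bool update_sigma_a,
                const bool update_sigma_e, const bool update_mu,
                const bool shuffle,
                const double w_init,
                const NumericVector& sigma2_a_init,
                const NumericVector& sigma2_e_init,
                const NumericVector& mu_init,
                const int check_every,
                const bool keep_samples) {
  const int n = X.nrow(), m = X.ncol();
  if (m < 1) stop("at least one marker is required");
  if (n < 1) stop("at least one sample is required");

  // contiguous population blocks
  std::vector<int> pstart(n_pop, -1), pend(n_pop, -1);
  for (int i = 0; i < n; ++i) {
    int p = pop[i];
    if (p < 0 || p >= n_pop) stop("population index out of range");
    if (pstart[p] < 0) pstart[p] = i;
    else if (pend[p] != i) stop("samples of one population must be contiguous");
    pend[p] = i + 1;
  }
  std::vector<int> n_in_pop(n_pop), n_in_task(n_task, 0);
  for (int p = 0; p < n_pop; ++p) {
    if (pstart[p] < 0) stop("population %d has no samples", p + 1);
    n_in_pop[p] = pend[p] - pstart[p];
    n_in_task[task_of_pop[p]] += n_in_pop[p];
  }

  const double* Xp = X.begin();
  // x'x per marker and task
  std::vector<double> xtx((size_t)m * n_task, 0.0);
  for (int j = 0; j < m; ++j) {
    const double* col = Xp + (size_t)j * n;
    double* xx = &xtx[(size_t)j * n_task];
    for (int p = 0; p < n_pop; ++p) {
      double s = 0.0;
      for (int i = pstart[p]; i < pend[p]; ++i) s += col[i] * col[i];
      xx[task_of_pop[p]] += s;
    }
  }

  // state
  std::vector<double> mu(mu_init.begin(), mu_init.end());
  std::vector<double> s2a(sigma2_a_init.begin(), sigma2_a_init.end());
  std::vector<double> s2e(sigma2_e_init.begin(), sigma2_e_init.end());
  double w = w_init;
  std::vector<int> gamma(m, 0);
  std::vector<double> A((size_t)m * n_task, 0.0);  // effects, row j task t
  std::vector<double> e(n);
  double y_scale = 0.0;
  for (int i = 0; i < n; ++i) {
    e[i] = y[i] - mu[pop[i]];
    y_scale = std::max(y_scale, std::fabs(y[i]));
  }
  y_scale += 1.0;

  const int n_rec = (thin >= 1) ? (n_iter - burn_in) / thin : 0;
  if (n_rec < 1) stop("no post burn-in samples would be recorded");

  // accumulators
  std::vector<double> a_sum((size_t)m * n_task, 0.0), g_sum(m, 0.0);
  std::vector<double> mu_sum(n_pop, 0.0), s2a_sum(n_task, 0.0), s2e_sum(n_task, 0.0);
  double w_sum = 0.0;
  const int trace_cols = 3 + 2 * n_task + n_pop;
  NumericMatrix trace(n_rec, trace_cols);
  NumericMatrix g_samp, a_samp;
  if (keep_samples) {
    g_samp = NumericMatrix(n_rec, m);
    a_samp = NumericMatrix(n_rec, m * n_task);
  }
  double max_resid_err = 0.0;

  std::vector<int> order(m);
  for (int j = 0; j < m; ++j) order[j] = j;
  std::vector<double> dot(n_task), muhat(n_task), sighat2(n_task), a_new(n_task);
  int rec = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (shuffle) {
      for (int j = m - 1; j > 0; --j) {
        int r = (int)std::floor(unif_rand() * (j + 1));
        if (r > j) r = j;
        std::swap(order[j], order[r]);
      }
    }

    // Step 2: joint update of gamma_j and a_jk, residuals maintained
    for (int jj = 0; jj < m; ++jj) {
      const int j = order[jj];
      const double* col = Xp + (size_t)j * n;
      const double* xx = &xtx[(size_t)j * n_task];
      double* arow = &A[(size_t)j * n_task];

      for (int t = 0; t < n_task; ++t) dot[t] = 0.0;
      for (int p = 0; p < n_pop; ++p) {
        double s = 0.0;
        const double* ep = &e[0];
        for (int i = pstart[p]; i < pend[p]; ++i) s += col[i] * ep[i];
        dot[task_of_pop[p]] += s;
      }

      double log_q = std::log(w) - std::log1p(-w), ssq = 0.0;
      for (int t = 0; t < n_task; ++t) {
        const double ratio = s2e[t] / s2a[t];
        const double denom = xx[t] + ratio;
        const double xy = dot[t] + xx[t] * arow[t];  // x' y* from residuals
        muhat[t] = xy / denom;
        sighat2[t] = s2e[t] / denom;
        log_q += 0.5 * std::log1p(xx[t] * s2a[t] / s2e[t]);
        ssq += muhat[t] * muhat[t] / sighat2[t];
      }
      log_q -= 0.5 * ssq;

      const int g_new = (unif_rand() < incl_prob_from_logq(log_q)) ? 1 : 0;
      if (g_new) {
        for (int t = 0; t < n_task; ++t)
          a_new[t] = muhat[t] + std::sqrt(sighat2[t]) * norm_rand();
        for (int p = 0; p < n_pop; ++p) {
          const double d = a_new[task_of_pop[p]] - arow[task_of_pop[p]];
          double* ep = &e[0];
          for (int i = pstart[p]; i < pend[p]; ++i) ep[i] -= col[i] * d;
        }
        for (int t = 0; t < n_task; ++t) arow[t] = a_new[t];
      } else if (gamma[j]) {
        for (int p = 0; p < n_pop; ++p) {
          const double d = arow[task_of_pop[p]];
          double* ep = &e[0];
          for (int i = pstart[p]; i < pend[p]; ++i) ep[i] += col[i] * d;
        }
        for (int t = 0; t < n_task; ++t) arow[t] = 0.0;
      }
      gamma[j] = g_new;
    }

    int sg = 0;
    for (int j = 0; j < m; ++j) sg += gamma[j];

    // Step 3: w (exclusion probability)
    if (update_w) {
      double alpha = (double)(m - sg), beta = (double)sg;
      if (w_plus_one) { alpha += 1.0; beta += 1.0; }
      else { if (alpha < 1e-8) alpha = 1e-8; if (beta < 1e-8) beta = 1e-8; }
      w = R::rbeta(alpha, beta);
      if (w < 1e-12) w = 1e-12;
      if (w > 1.0 - 1e-12) w = 1.0 - 1e-12;
    }

    // Step 4: sigma2_a per task
    if (update_sigma_a) {
      for (int t = 0; t < n_task; ++t) {
        double ssa = 0.0;
        for (int j = 0; j < m; ++j) {
          const double a = A[(size_t)j * n_task + t];
          ssa += a * a;
        }
        const double df = v_a[t] + sg;
        const double scale = (v_a[t] * s2_a[t] + ssa) / df;
        s2a[t] = df * scale / R::rchisq(df);
        check_variance(s2a[t], "sigma2_a");
      }
    }

    // Step 5: sigma2_e per task
    if (update_sigma_e) {
      std::vector<double> sse(n_task, 0.0);
      for (int p = 0; p < n_pop; ++p) {
        double s = 0.0;
        for (int i = pstart[p]; i < pend[p]; ++i) s += e[i] * e[i];
        sse[task_of_pop[p]] += s;
      }
      for (int t = 0; t < n_task; ++t) {
        const double df = v_e[t] + n_in_task[t];
        const double scale = (v_e[t] * s2_e[t] + sse[t]) / df;
        s2e[t] = df * scale / R::rchisq(df);
        check_variance(s2e[t], "sigma2_e");
      }
    }

    // Step 6: mu per population, residuals shifted
    if (update_mu) {
      for (int p = 0; p < n_pop; ++p) {
        double esum = 0.0;
        for (int i = pstart[p]; i < pend[p]; ++i) esum += e[i];
        const double sd = std::sqrt(s2e[task_of_pop[p]] / n_in_pop[p]);
        const double mu_new = mu[p] + esum / n_in_pop[p] + sd * norm_rand();
        const double shift = mu_new - mu[p];
        mu[p] = mu_new;
        for (int i = pstart[p]; i < pend[p]; ++i) e[i] -= shift;
      }
    }

    // record
    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      for (size_t u = 0; u < A.size(); ++u) a_sum[u] += A[u];
      for (int j = 0; j < m; ++j) g_sum[j] += gamma[j];
      for (int p = 0; p < n_pop; ++p) mu_sum[p] += mu[p];
      for (int t = 0; t < n_task; ++t) { s2a_sum[t] += s2a[t]; s2e_sum[t] += s2e[t]; }
      w_sum += w;
      if (rec < n_rec) {
        trace(rec, 0) = iter;
        trace(rec, 1) = sg;
        trace(rec, 2) = w;
        for (int t = 0; t < n_task; ++t) {
          trace(rec, 3 + t) = s2a[t];
          trace(rec, 3 + n_task + t) = s2e[t];
        }
        for (int p = 0; p < n_pop; ++p) trace(rec, 3 + 2 * n_task + p) = mu[p];
        if (keep_samples) {
          for (int j = 0; j < m; ++j) g_samp(rec, j) = gamma[j];
          for (int j = 0; j < m; ++j)
            for (int t = 0; t < n_task; ++t)
              a_samp(rec, j * n_task + t) = A[(size_t)j * n_task + t];
        }
      }
      ++rec;
    }

    // residual bookkeeping audit against a from-scratch recomputation
    if (check_every > 0 && (iter % check_every == 0 || iter == n_iter)) {
      std::vector<double> r(n);
      for (int i = 0; i < n; ++i) r[i] = y[i] - mu[pop[i]];
      for (int j = 0; j < m; ++j) {
        if (!gamma[j]) continue;
        const double* col = Xp + (size_t)j * n;
        const double* arow = &A[(size_t)j * n_task];
        for (int p = 0; p < n_pop; ++p) {
          const double a = arow[task_of_pop[p]];
          for (int i = pstart[p]; i < pend[p]; ++i) r[i] -= col[i] * a;
        }
      }
      for (int i = 0; i < n; ++i) {
        const double d = std::fabs(r[i] - e[i]) / y_scale;
        if (d > max_resid_err) max_resid_err = d;
      }
    }
  }

  const double inv = 1.0 / (double)n_rec;
  NumericMatrix effect_mean(m, n_task);
  NumericVector incl(m), mu_mean(n_pop), s2a_mean(n_task), s2e_mean(n_task);
  for (int j = 0; j < m; ++j) {
    incl[j] = g_sum[j] * inv;
    for (int t = 0; t < n_task; ++t)
      effect_mean(j, t) = a_sum[(size_t)j * n_task + t] * inv;
  }
  for (int p = 0; p < n_pop; ++p) mu_mean[p] = mu_sum[p] * inv;
  for (int t = 0; t < n_task; ++t) {
    s2a_mean[t] = s2a_sum[t] * inv;
    s2e_mean[t] = s2e_sum[t] * inv;
  }

  List out = List::create(
    _["effect_mean"] = effect_mean,
    _["inclusion_prob"] = incl,
    _["mu_mean"] = mu_mean,
    _["w_mean"] = w_sum * inv,
    _["sigma2_a_mean"] = s2a_mean,
    _["sigma2_e_mean"] = s2e_mean,
    _["n_samples_used"] = n_rec,
    _["trace"] = trace,
    _["max_residual_error"] = max_resid_err);
  if (keep_samples) {
    out["gamma_samples"] = g_samp;
    out["effect_samples"] = a_samp;
  }
  return out;
}
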