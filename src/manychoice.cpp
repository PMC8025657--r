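// Core likelihood and simulation routines.
//
// Trials are passed as R lists prepared by trial_model_input():
//   l       numeric[N]   rescaled item values (1..7)
//   ms_item integer[T]   item gazed during millisecond t (1-based; 0 = none),
//                        T = end of the observed/scaffolded gaze stream
//   g       numeric[N]   cumulative gaze fraction at rt (GLAM)
//   g_rem   numeric[N]   gaze fraction of remaining trial time after first
//                        gaze (IAM), clamped to [0, 1]; NA for unseen
//   t0      numeric[N]   first-gaze onset in ms; -1 for unseen
//   rt      double       response time in ms
//   choice  int          1-based chosen item
//   N       int          set size
//
// All times are integer milliseconds; the model grid is dt = 1 ms.

#include <Rcpp.h>
using namespace Rcpp;

static const double MIX_MODEL = 0.95;
static const double MIX_CONTAM = 0.05;

// ---------------------------------------------------------------------------
// Probabilistic satisficing model (PSM)
// ---------------------------------------------------------------------------

// Per-ms state for the PSM: cumulative gaze counts per item, the set of
// seen items in first-seen order, and gaze-weighted cached values
//   c_i(t) = g_i(t) (l_i + zeta) + (1 - g_i(t)) gamma l_i  (seen items).
// The stopping hazard is q(t) = min(alpha * max_i c_i(t) + v t, 1) once at
// least one item has been seen, and 0 before (the softmax choice rule is
// undefined on an empty seen set).
struct PsmState {
  int N;
  const int *ms_item; // 0-based array, entries 1..N or 0
  int T;              // stream length
  const double *l;
  double gamma, zeta;
  std::vector<double> G;      // cumulative gaze ms per item
  std::vector<int> seen;      // seen items (1-based), first-seen order
  std::vector<bool> is_seen;
  std::vector<double> c;      // cached values, updated per ms
  std::vector<double> gfroz;  // frozen g_i beyond the stream, lazily set
  bool frozen;

  PsmState(int N_, const int *ms, int T_, const double *l_,
           double gamma_, double zeta_)
    : N(N_), ms_item(ms), T(T_), l(l_), gamma(gamma_), zeta(zeta_),
      G(N_, 0.0), is_seen(N_, false), c(N_, 0.0), gfroz(N_, 0.0),
      frozen(false) {}

  // advance to millisecond t (1-based); call with t = 1, 2, ...
  void step(int t) {
    if (t <= T) {
      int it = ms_item[t - 1];
      if (it >= 1) {
        G[it - 1] += 1.0;
        if (!is_seen[it - 1]) {
          is_seen[it - 1] = true;
          seen.push_back(it);
        }
      }
      double td = (double)t;
      for (size_t k = 0; k < seen.size(); ++k) {
        int i = seen[k] - 1;
        double g = G[i] / td;
        c[i] = g * (l[i] + zeta) + (1.0 - g) * gamma * l[i];
      }
    } else if (!frozen) {
      // freeze gaze fractions at their end-of-stream values
      double td = (double)T;
      for (size_t k = 0; k < seen.size(); ++k) {
        int i = seen[k] - 1;
        double g = (td > 0) ? G[i] / td : 0.0;
        c[i] = g * (l[i] + zeta) + (1.0 - g) * gamma * l[i];
      }
      frozen = true;
    }
  }

  double hazard(int t, double v, double alpha) const {
    if (seen.empty()) return 0.0;
    double C = R_NegInf;
    for (size_t k = 0; k < seen.size(); ++k) {
      double ci = c[seen[k] - 1];
      if (ci > C) C = ci;
    }
    double q = alpha * C + v * (double)t;
    if (q < 0.0) q = 0.0;
    if (q > 1.0) q = 1.0;
    return q;
  }

  // softmax choice probability over seen items at the current state
  double choice_prob(int item, double tau) const {
    if (seen.empty()) return 0.0;
    if (!is_seen[item - 1]) return 0.0;
    double cmax = R_NegInf;
    for (size_t k = 0; k < seen.size(); ++k)
      cmax = std::max(cmax, c[seen[k] - 1]);
    double denom = 0.0;
    for (size_t k = 0; k < seen.size(); ++k)
      denom += std::exp(tau * (c[seen[k] - 1] - cmax));
    return std::exp(tau * (c[item - 1] - cmax)) / denom;
  }

  void softmax(double tau, std::vector<double> &out) const {
    std::fill(out.begin(), out.end(), 0.0);
    if (seen.empty()) return;
    double cmax = R_NegInf;
    for (size_t k = 0; k < seen.size(); ++k)
      cmax = std::max(cmax, c[seen[k] - 1]);
    double denom = 0.0;
    for (size_t k = 0; k < seen.size(); ++k)
      denom += std::exp(tau * (c[seen[k] - 1] - cmax));
    for (size_t k = 0; k < seen.size(); ++k) {
      int i = seen[k] - 1;
      out[i] = std::exp(tau * (c[i] - cmax)) / denom;
    }
  }
};

// Per-trial PSM log likelihood under the 95/5 contaminant mixture:
// log(0.95 f(rt) sigma_choice(rt) + 0.05 u).
// [[Rcpp::export]]
NumericVector cpp_psm_loglik(List trials, double v, double alpha, double tau,
                             double gamma, double zeta, NumericVector us) {
  int ntr = trials.size();
  NumericVector out(ntr);
  for (int j = 0; j < ntr; ++j) {
    List tr = trials[j];
    NumericVector l = tr["l"];
    IntegerVector ms = tr["ms_item"];
    int rt = (int)Rf_asReal(tr["rt"]);
    int choice = Rf_asInteger(tr["choice"]);
    PsmState st(l.size(), ms.begin(), ms.size(), l.begin(), gamma, zeta);
    double logQ = 0.0; // log prod_{s<t} (1 - q(s))
    double p = 0.0;
    bool dead = false;
    for (int t = 1; t <= rt; ++t) {
      st.step(t);
      double q = st.hazard(t, v, alpha);
      if (t == rt) {
        double f = q * std::exp(logQ);
        p = f * st.choice_prob(choice, tau);
      } else {
        if (q >= 1.0) { dead = true; break; } // search surely over before rt
        logQ += std::log1p(-q);
      }
    }
    if (dead) p = 0.0;
    out[j] = std::log(MIX_MODEL * p + MIX_CONTAM * us[j]);
  }
  return out;
}

// Stopping-time density f(t), survival Q(t), hazard q(t) and per-item
// choice probabilities integrated over t, on t = 1..horizon ms.
// [[Rcpp::export]]
List cpp_psm_density(List trial, double v, double alpha, double tau,
                     double gamma, double zeta, int horizon) {
  List tr = trial;
  NumericVector l = tr["l"];
  IntegerVector ms = tr["ms_item"];
  int N = l.size();
  PsmState st(N, ms.begin(), ms.size(), l.begin(), gamma, zeta);
  NumericVector f(horizon), q_out(horizon), Q_out(horizon);
  NumericVector p_choice(N);
  std::vector<double> sm(N);
  double logQ = 0.0;
  bool done = false;
  for (int t = 1; t <= horizon; ++t) {
    if (done) { f[t - 1] = 0.0; q_out[t - 1] = 1.0; Q_out[t - 1] = 0.0; continue; }
    st.step(t);
    double q = st.hazard(t, v, alpha);
    double ft = q * std::exp(logQ);
    f[t - 1] = ft;
    q_out[t - 1] = q;
    if (ft > 0.0) {
      st.softmax(tau, sm);
      for (int i = 0; i < N; ++i) p_choice[i] += ft * sm[i];
    }
    if (q >= 1.0) { done = true; Q_out[t - 1] = 0.0; }
    else { logQ += std::log1p(-q); Q_out[t - 1] = std::exp(logQ); }
  }
  return List::create(_["f"] = f, _["q"] = q_out, _["Q"] = Q_out,
                      _["p_choice"] = p_choice);
}

// Forward simulation: at each millisecond the search stops with
// probability q(t); on stopping, the choice is drawn from the softmax
// over the seen items' cached values. Gaze fractions are frozen at
// their final observed value beyond the end of the gaze stream.
// [[Rcpp::export]]
IntegerMatrix cpp_psm_simulate(List trial, double v, double alpha, double tau,
                               double gamma, double zeta, int n_reps,
                               int horizon) {
  List tr = trial;
  NumericVector l = tr["l"];
  IntegerVector ms = tr["ms_item"];
  int N = l.size();
  // Precompute hazards and cached values per ms (shared across reps).
  PsmState st(N, ms.begin(), ms.size(), l.begin(), gamma, zeta);
  std::vector<double> qv(horizon);
  std::vector<std::vector<double> > cmat; // softmax probs per ms (lazy: store c)
  NumericMatrix cvals(horizon, N);
  std::vector<int> nseen(horizon);
  for (int t = 1; t <= horizon; ++t) {
    st.step(t);
    qv[t - 1] = st.hazard(t, v, alpha);
    for (int i = 0; i < N; ++i)
      cvals(t - 1, i) = st.is_seen[i] ? st.c[i] : NA_REAL;
    nseen[t - 1] = (int)st.seen.size();
  }
  IntegerMatrix out(n_reps, 2);
  GetRNGstate();
  for (int r = 0; r < n_reps; ++r) {
    int stop_t = -1;
    for (int t = 1; t <= horizon; ++t) {
      double q = qv[t - 1];
      if (q > 0.0 && (q >= 1.0 || unif_rand() < q)) { stop_t = t; break; }
    }
    if (stop_t < 0) {
      PutRNGstate();
      stop("simulation horizon exceeded without stopping; increase the "
           "horizon or check that v > 0 or alpha > 0");
    }
    // softmax draw over seen items at stop_t
    double cmax = R_NegInf;
    for (int i = 0; i < N; ++i) {
      double ci = cvals(stop_t - 1, i);
      if (!ISNA(ci) && ci > cmax) cmax = ci;
    }
    double denom = 0.0;
    for (int i = 0; i < N; ++i) {
      double ci = cvals(stop_t - 1, i);
      if (!ISNA(ci)) denom += std::exp(tau * (ci - cmax));
    }
    double u = unif_rand() * denom, acc = 0.0;
    int pick = -1;
    for (int i = 0; i < N; ++i) {
      double ci = cvals(stop_t - 1, i);
      if (ISNA(ci)) continue;
      acc += std::exp(tau * (ci - cmax));
      if (u <= acc) { pick = i + 1; break; }
    }
    if (pick < 0) { // numerical slack: last seen item
      for (int i = N - 1; i >= 0; --i)
        if (!ISNA(cvals(stop_t - 1, i))) { pick = i + 1; break; }
    }
    out(r, 0) = pick;
    out(r, 1) = stop_t;
  }
  PutRNGstate();
  return out;
}

// ---------------------------------------------------------------------------
// Inverse Gaussian first-passage-time distribution
// ---------------------------------------------------------------------------

// log density of IG(mu, lambda) at t > 0
static double ig_logpdf(double t, double mu, double lambda) {
  if (t <= 0.0 || mu <= 0.0 || lambda <= 0.0) return R_NegInf;
  double d = t - mu;
  return 0.5 * (std::log(lambda) - std::log(2.0 * M_PI) - 3.0 * std::log(t))
       - lambda * d * d / (2.0 * mu * mu * t);
}

// log CDF, numerically stable via log-space combination of the two
// normal terms (the exp(2 lambda / mu) factor overflows otherwise)
static double ig_logcdf(double t, double mu, double lambda) {
  if (t <= 0.0) return R_NegInf;
  double sq = std::sqrt(lambda / t);
  double z1 = sq * (t / mu - 1.0);
  double z2 = -sq * (t / mu + 1.0);
  double la = R::pnorm(z1, 0.0, 1.0, 1, 1);            // log Phi(z1)
  double lb = 2.0 * lambda / mu + R::pnorm(z2, 0.0, 1.0, 1, 1);
  double m = std::max(la, lb);
  double logF = m + std::log(std::exp(la - m) + std::exp(lb - m));
  return std::min(logF, 0.0);
}

// log survival log(1 - F(t)); 1 - F = Phi(-z1) - e^{2 lambda/mu} Phi(z2)
static double ig_logsurv(double t, double mu, double lambda) {
  if (t <= 0.0) return 0.0;
  double sq = std::sqrt(lambda / t);
  double z1 = sq * (t / mu - 1.0);
  double z2 = -sq * (t / mu + 1.0);
  double la = R::pnorm(-z1, 0.0, 1.0, 1, 1);           // log Phi(-z1)
  double lb = 2.0 * lambda / mu + R::pnorm(z2, 0.0, 1.0, 1, 1);
  if (lb >= la) return R_NegInf; // survival underflows to 0
  return la + std::log1p(-std::exp(lb - la));
}

// [[Rcpp::export]]
NumericVector cpp_ig_logpdf(NumericVector t, double mu, double lambda) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ig_logpdf(t[i], mu, lambda);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_ig_logcdf(NumericVector t, double mu, double lambda) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ig_logcdf(t[i], mu, lambda);
  return out;
}

// Michael-Schucany-Haas sampler, driven by R's RNG
// [[Rcpp::export]]
NumericVector cpp_ig_sample(int n, double mu, double lambda) {
  NumericVector out(n);
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    double nu = norm_rand();
    double y = nu * nu;
    // smaller root of the quadratic, written in a cancellation-free
    // form: x = mu (1 + c - sqrt(c (c + 2))) = mu / (1 + c + sqrt(c (c + 2)))
    double c = mu * y / (2.0 * lambda);
    double x = mu / (1.0 + c + std::sqrt(c * (c + 2.0)));
    double u = unif_rand();
    out[i] = (u <= mu / (mu + x)) ? x : mu * mu / x;
  }
  PutRNGstate();
  return out;
}

// ---------------------------------------------------------------------------
// Race models (IAM and GLAM): accumulator drift rates and likelihoods
// ---------------------------------------------------------------------------

// Drift signals D_i for the seen items. model = 0: IAM, using the
// remaining-trial-time gaze fraction g_rem; model = 1: GLAM, using the
// whole-trial gaze fraction g, relative signals, and a logistic
// transform with scale tau.
static void race_drifts(const NumericVector &l, const NumericVector &g,
                        const NumericVector &g_rem, const LogicalVector &seen,
                        double gamma, double zeta, double tau, int model,
                        std::vector<double> &D) {
  int N = l.size();
  D.assign(N, 0.0);
  if (model == 0) {
    for (int i = 0; i < N; ++i) {
      if (!seen[i]) continue;
      double gi = g_rem[i];
      D[i] = gi * (l[i] + zeta) + (1.0 - gi) * gamma * l[i];
    }
  } else {
    std::vector<double> A(N, R_NegInf);
    int nseen = 0;
    for (int i = 0; i < N; ++i) {
      if (!seen[i]) continue;
      A[i] = g[i] * (l[i] + zeta) + (1.0 - g[i]) * gamma * l[i];
      ++nseen;
    }
    for (int i = 0; i < N; ++i) {
      if (!seen[i]) continue;
      double R_i = 0.0; // singleton seen set: relative signal defined as 0
      if (nseen > 1) {
        double mx = R_NegInf;
        for (int j = 0; j < N; ++j)
          if (j != i && seen[j] && A[j] > mx) mx = A[j];
        R_i = A[i] - mx;
      }
      D[i] = 1.0 / (1.0 + std::exp(-tau * R_i));
    }
  }
}

// Per-trial race log likelihood under the contaminant mixture.
// p_i(rt) = f_i(rt - t0_i) prod_{j != i, seen} (1 - F_j(rt - t0_j)),
// with t0 = 0 for the GLAM (all accumulators start at stimulus onset)
// and mu_i = b / (v D_i), lambda = b^2 / sigma^2, b = 1.
// [[Rcpp::export]]
NumericVector cpp_race_loglik(List trials, double v, double sigma,
                              double gamma, double zeta, double tau,
                              int model, NumericVector us) {
  int ntr = trials.size();
  double lambda = 1.0 / (sigma * sigma);
  NumericVector out(ntr);
  std::vector<double> D;
  for (int j = 0; j < ntr; ++j) {
    List tr = trials[j];
    NumericVector l = tr["l"];
    NumericVector g = tr["g"];
    NumericVector g_rem = tr["g_rem"];
    NumericVector t0 = tr["t0"];
    LogicalVector seen = tr["seen"];
    double rt = Rf_asReal(tr["rt"]);
    int choice = Rf_asInteger(tr["choice"]) - 1;
    int N = l.size();
    race_drifts(l, g, g_rem, seen, gamma, zeta, tau, model, D);
    double logp;
    double tc = (model == 0) ? rt - t0[choice] : rt;
    if (!seen[choice] || tc <= 0.0 || D[choice] <= 0.0) {
      logp = R_NegInf;
    } else {
      logp = ig_logpdf(tc, 1.0 / (v * D[choice]), lambda);
      for (int i = 0; i < N; ++i) {
        if (i == choice || !seen[i] || D[i] <= 0.0) continue;
        double ti = (model == 0) ? rt - t0[i] : rt;
        if (ti <= 0.0) continue; // accumulator not yet started: survival 1
        logp += ig_logsurv(ti, 1.0 / (v * D[i]), lambda);
      }
    }
    double p = std::exp(logp);
    out[j] = std::log(MIX_MODEL * p + MIX_CONTAM * us[j]);
  }
  return out;
}

// Joint density over the grid t = dt, 2dt, ..., horizon: per-item choice
// probabilities (integrated) and the RT density marginal. Used for
// normalization checks and as the closed-form side of the
// simulator-vs-likelihood comparison.
// [[Rcpp::export]]
List cpp_race_density(List trial, double v, double sigma, double gamma,
                      double zeta, double tau, int model, double dt,
                      double horizon) {
  List tr = trial;
  NumericVector l = tr["l"];
  NumericVector g = tr["g"];
  NumericVector g_rem = tr["g_rem"];
  NumericVector t0 = tr["t0"];
  LogicalVector seen = tr["seen"];
  int N = l.size();
  double lambda = 1.0 / (sigma * sigma);
  std::vector<double> D;
  race_drifts(l, g, g_rem, seen, gamma, zeta, tau, model, D);
  int nt = (int)std::floor(horizon / dt);
  NumericVector rt_dens(nt), p_choice(N), tgrid(nt);
  for (int k = 0; k < nt; ++k) {
    double t = dt * (k + 1);
    tgrid[k] = t;
    for (int i = 0; i < N; ++i) {
      if (!seen[i] || D[i] <= 0.0) continue;
      double ti = (model == 0) ? t - t0[i] : t;
      if (ti <= 0.0) continue;
      double lp = ig_logpdf(ti, 1.0 / (v * D[i]), lambda);
      for (int j2 = 0; j2 < N; ++j2) {
        if (j2 == i || !seen[j2] || D[j2] <= 0.0) continue;
        double tj = (model == 0) ? t - t0[j2] : t;
        if (tj <= 0.0) continue;
        lp += ig_logsurv(tj, 1.0 / (v * D[j2]), lambda);
      }
      double pit = std::exp(lp);
      rt_dens[k] += pit;
      p_choice[i] += pit * dt;
    }
  }
  return List::create(_["t_ms"] = tgrid, _["rt_density"] = rt_dens,
                      _["p_choice"] = p_choice, _["drift"] = wrap(D));
}
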