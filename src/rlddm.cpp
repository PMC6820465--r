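#include <Rcpp.h>
using namespace Rcpp;

// First-passage density of a unit-variance Wiener process between absorbing
// boundaries 0 and a, start a*w, drift v, evaluated at decision time t at the
// LOWER boundary. Uses the standardized-time density f(t/a^2; 0, 1, w) with
// small-time and large-time series; the representation with fewer terms for
// the requested truncation error is selected per evaluation.

static double ftau_std(double tau, double w, double err) {
  // number of terms needed by each expansion
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * err * std::sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tau * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * err) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double f = 0.0;
  if (ks < kl) {          // small-time expansion
    int K = (int) std::ceil(ks);
    int lo = -(int) std::floor((K - 1.0) / 2.0);
    int hi =  (int) std::ceil((K - 1.0) / 2.0);
    for (int k = lo; k <= hi; k++) {
      double z = w + 2.0 * k;
      f += z * std::exp(-z * z / (2.0 * tau));
    }
    f /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {                // large-time expansion
    int K = (int) std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      f += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f;
}

static double wfpt_ld_one(double rt, int upper, double v, double a,
                          double ter, double w, double tol) {
  if (!R_finite(v) || !R_finite(a) || !R_finite(ter))
    stop("non-finite diffusion parameters");
  if (a <= 0.0) stop("threshold must be positive");
  double t = rt - ter;
  if (!R_finite(rt) || t <= 0.0) return R_NegInf;
  double vv = v, ww = w;
  if (upper) { vv = -v; ww = 1.0 - w; }   // reflection: upper density from lower form
  double tau = t / (a * a);
  double f = ftau_std(tau, ww, tol);
  if (f <= 0.0) return R_NegInf;
  return std::log(f) - vv * a * ww - vv * vv * t / 2.0 - 2.0 * std::log(a);
}

// [[Rcpp::export]]
NumericVector wfpt_logdens_cpp(NumericVector rt, IntegerVector upper,
                               NumericVector v, NumericVector a,
                               NumericVector ter, double w, double tol) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double vi  = v.size()  == 1 ? v[0]  : v[i];
    double ai  = a.size()  == 1 ? a[0]  : a[i];
    double ti  = ter.size() == 1 ? ter[0] : ter[i];
    out[i] = wfpt_ld_one(rt[i], upper[i], vi, ai, ti, w, tol);
  }
  return out;
}

// Euler-Maruyama simulation of the bounded accumulator, one first-passage
// sample per element of v/a. A Brownian-bridge correction detects
// within-step boundary crossings that the discrete skeleton misses,
// removing the leading sqrt(dt) bias of naive Euler crossing detection.
// Uses the R RNG so set.seed() governs draws.
// [[Rcpp::export]]
DataFrame sim_fp_cpp(NumericVector v, NumericVector a, NumericVector ter,
                     double dt, double max_time) {
  int n = std::max(v.size(), a.size());
  NumericVector rt(n);
  IntegerVector up(n);
  LogicalVector censored(n);
  double sdt = std::sqrt(dt);
  RNGScope scope;
  for (int i = 0; i < n; i++) {
    double vi = v.size() == 1 ? v[0] : v[i];
    double ai = a.size() == 1 ? a[0] : a[i];
    double ti = ter.size() == 1 ? ter[0] : ter[i];
    if (ai <= 0.0) stop("threshold must be positive");
    double x = ai / 2.0;
    double t = 0.0;
    int hit = NA_INTEGER;
    bool cens = true;
    while (t < max_time) {
      double x1 = x + vi * dt + sdt * norm_rand();
      t += dt;
      if (x1 >= ai) { hit = 1; cens = false; break; }
      if (x1 <= 0.0) { hit = 0; cens = false; break; }
      // bridge probability that the path crossed a boundary inside the step
      double p_up = std::exp(-2.0 * (ai - x) * (ai - x1) / dt);
      double p_dn = std::exp(-2.0 * x * x1 / dt);
      double u = unif_rand();
      if (u < p_up) { hit = 1; cens = false; break; }
      if (u < p_up + p_dn) { hit = 0; cens = false; break; }
      x = x1;
    }
    rt[i] = cens ? NA_REAL : t + ti;
    up[i] = hit;
    censored[i] = cens;
  }
  return DataFrame::create(_["rt"] = rt, _["upper"] = up, _["censored"] = censored);
}

// Delta-rule trajectory under full feedback: both presented options are
// updated each trial with their own feedback; prediction-error sign selects
// the learning rate (ties use eta_plus). Returns the values ENTERING each
// trial (updated through the previous trial) and presentation counts
// including the current trial.
// [[Rcpp::export]]
List q_traj_cpp(IntegerVector block, IntegerVector o_cor, IntegerVector o_inc,
                NumericVector f_cor, NumericVector f_inc,
                double eta_plus, double eta_minus,
                double q0, int grand_mean_init, int n_options) {
  int n = block.size();
  NumericVector qc(n), qi(n);
  IntegerVector nc(n), ni(n);
  std::vector<double> q(n_options, q0);
  std::vector<int> cnt(n_options, 0);
  int cur_block = n > 0 ? block[0] : 1;
  for (int t = 0; t < n; t++) {
    if (block[t] != cur_block) {     // new block: new stimuli, carry prior knowledge
      cur_block = block[t];
      if (grand_mean_init) {
        double m = 0.0;
        for (int j = 0; j < n_options; j++) m += q[j];
        m /= n_options;
        for (int j = 0; j < n_options; j++) q[j] = m;
      }
      for (int j = 0; j < n_options; j++) cnt[j] = 0;
    }
    int a = o_cor[t] - 1, b = o_inc[t] - 1;
    if (a < 0 || a >= n_options || b < 0 || b >= n_options)
      stop("option index out of range at trial %d", t + 1);
    qc[t] = q[a];
    qi[t] = q[b];
    cnt[a]++; cnt[b]++;
    nc[t] = cnt[a];
    ni[t] = cnt[b];
    double pe_a = f_cor[t] - q[a];
    double pe_b = f_inc[t] - q[b];
    q[a] += (pe_a >= 0.0 ? eta_plus : eta_minus) * pe_a;
    q[b] += (pe_b >= 0.0 ? eta_plus : eta_minus) * pe_b;
  }
  return List::create(_["q_cor"] = qc, _["q_inc"] = qi,
                      _["n_cor"] = nc, _["n_inc"] = ni);
}
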