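#include <Rcpp.h>
using namespace Rcpp;

// Trial-level Monte Carlo simulators for reaction-time tasks.  These mirror
// the R-level integrator (fixed-step RK4 with a per-unit Ornstein-Uhlenbeck
// noise current held fixed within the step, non-negativity clamp after each
// full step) but are specialized to two alternatives for speed: quantile
// maximum likelihood fitting evaluates ~1e4 simulated trials per objective
// call.

// Counter-seeded xoshiro256+ generator with Marsaglia polar normals.  The
// simulators draw millions of normals per likelihood evaluation; a local
// generator keeps that cheap and makes every batch a pure function of its
// seed argument (exact common random numbers during fitting).
struct Rng {
  uint64_t s[4];
  double spare;
  bool has_spare;
  explicit Rng(uint64_t seed) : has_spare(false) {
    // splitmix64 expansion of the seed
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97F4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  inline uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = (s[3] << 45) | (s[3] >> 19);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    const double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// OU update: n <- n + (dt/tau) * (-n) + sigma * sqrt(dt/tau) * eta.
// Stationary SD approaches sigma/sqrt(2) as dt/tau -> 0.
static inline double ou_step(double n, double kdt, double amp, Rng &rng) {
  return n - kdt * n + amp * rng.norm();
}

struct LddmDeriv {
  double alpha, beta, BR, BG, w, v, tauR, tauG, tauD;
  double V1, V2;
  // y = (R1, R2, G1, G2, D1, D2); nz = per-unit OU noise currents, held
  // fixed within a step
  inline void operator()(const double *y, const double *nz,
                         double *dy) const {
    dy[0] = (-y[0] + (V1 + alpha * y[0] + BR) / (1.0 + y[2]) + nz[0]) / tauR;
    dy[1] = (-y[1] + (V2 + alpha * y[1] + BR) / (1.0 + y[3]) + nz[1]) / tauR;
    dy[2] = (-y[2] + w * y[0] + v * y[1] + BG - y[4] + nz[2]) / tauG;
    dy[3] = (-y[3] + v * y[0] + w * y[1] + BG - y[5] + nz[3]) / tauG;
    dy[4] = (-y[4] + beta * y[0] + nz[4]) / tauD;
    dy[5] = (-y[5] + beta * y[1] + nz[5]) / tauD;
  }
};

// One step: RK4 with the OU noise current frozen, clamp, then refresh the
// noise states.
static inline void rk4_step(const LddmDeriv &f, double *y, const double *nz,
                            double dt) {
  double k1[6], k2[6], k3[6], k4[6], tmp[6];
  f(y, nz, k1);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  f(tmp, nz, k2);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  f(tmp, nz, k3);
  for (int i = 0; i < 6; ++i) tmp[i] = y[i] + dt * k3[i];
  f(tmp, nz, k4);
  for (int i = 0; i < 6; ++i) {
    y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    if (y[i] < 0.0) y[i] = 0.0;
  }
}

// Simulate n two-alternative trials of the disinhibition circuit in a
// reaction-time protocol: a gap stage (zero input, gate off) followed by a
// stimulus stage (V1, V2, gate on).  Returns a matrix with columns
// rt (threshold-crossing time from stimulus onset, s; NA if censored) and
// choice (1 or 2; 0 if censored).
// [[Rcpp::export]]
NumericMatrix cpp_lddm_trials(int n, double V1, double V2, double alpha,
                              double beta, double BR, double BG, double sigma,
                              double tauR, double tauG, double tauD,
                              double tau_noise, double w, double v, double dt,
                              double gap, double fixdur, double thresh,
                              double cutoff, double r0, bool g0_matched,
                              int seed) {
  NumericMatrix out(n, 2);
  Rng rng((uint64_t)seed);
  const int n_gap = (int)std::lround(gap / dt);
  const int n_fix = (int)std::lround(fixdur / dt);
  const int n_max = (int)std::lround(cutoff / dt);
  const double kdt = dt / tau_noise;
  const double amp = sigma * std::sqrt(dt / tau_noise);
  LddmDeriv fgap{alpha, 0.0, BR, BG, w, v, tauR, tauG, tauD, 0.0, 0.0};
  LddmDeriv fview{alpha, 0.0, BR, BG, w, v, tauR, tauG, tauD, V1, V2};
  LddmDeriv fstim{alpha, beta, BR, BG, w, v, tauR, tauG, tauD, V1, V2};
  for (int t = 0; t < n; ++t) {
    double y[6], nz[6] = {0, 0, 0, 0, 0, 0};
    y[0] = y[1] = r0;
    y[2] = y[3] = g0_matched ? (w * r0 + v * r0 + BG) : 0.0;
    if (y[2] < 0.0) y[2] = y[3] = 0.0;
    y[4] = y[5] = 0.0;
    for (int s = 0; s < n_gap + n_fix; ++s) {
      rk4_step(s < n_gap ? fgap : fview, y, nz, dt);
      if (sigma > 0.0)
        for (int i = 0; i < 6; ++i) nz[i] = ou_step(nz[i], kdt, amp, rng);
    }
    double rt = NA_REAL;
    int choice = 0;
    for (int s = 1; s <= n_max; ++s) {
      rk4_step(fstim, y, nz, dt);
      if (sigma > 0.0)
        for (int i = 0; i < 6; ++i) nz[i] = ou_step(nz[i], kdt, amp, rng);
      if (y[0] >= thresh || y[1] >= thresh) {
        choice = (y[0] >= y[1]) ? 1 : 2;
        rt = gap + fixdur + s * dt;
        break;
      }
    }
    out(t, 0) = rt;
    out(t, 1) = choice;
  }
  return out;
}

// Effective transfer function of the reduced two-variable recurrent network:
// H(x) = (a x - b) / (1 - exp(-d (a x - b))), with the removable singularity
// H = 1/d at a x = b.
static inline double ww_H(double x, double a, double b, double d) {
  double u = a * x - b;
  if (std::fabs(d * u) < 1e-9) return 1.0 / d + u / 2.0;
  return u / (1.0 - std::exp(-d * u));
}

// Reduced recurrent network (two synaptic gating variables) reaction-time
// trials.  Input currents are mu0_eff * (1 +/- cprime); noise is an OU
// current per population with time constant tau_ampa.  Decision when either
// population rate H(x_i) crosses thresh.  rt is time from stimulus-input
// onset (gap handled by the caller as dead time).
// [[Rcpp::export]]
NumericMatrix cpp_rnm_trials(int n, double cprime, double jn_same,
                             double jn_diff, double I0, double sigma,
                             double mu0_eff, double gamma_kin, double s0,
                             double tauS, double a, double b, double d,
                             double tau_ampa, double dt, double thresh,
                             double cutoff, int seed) {
  NumericMatrix out(n, 2);
  Rng rng((uint64_t)seed);
  const int n_max = (int)std::lround(cutoff / dt);
  const double kdt = dt / tau_ampa;
  const double amp = sigma * std::sqrt(dt / tau_ampa);
  const double i1 = mu0_eff * (1.0 + cprime), i2 = mu0_eff * (1.0 - cprime);
  for (int t = 0; t < n; ++t) {
    double s1 = s0, s2 = s0, n1 = 0.0, n2 = 0.0;
    double rt = NA_REAL;
    int choice = 0;
    for (int s = 1; s <= n_max; ++s) {
      double x1 = jn_same * s1 - jn_diff * s2 + I0 + i1 + n1;
      double x2 = jn_same * s2 - jn_diff * s1 + I0 + i2 + n2;
      double h1 = ww_H(x1, a, b, d), h2 = ww_H(x2, a, b, d);
      if (h1 < 0.0) h1 = 0.0;
      if (h2 < 0.0) h2 = 0.0;
      s1 += dt * (-s1 / tauS + (1.0 - s1) * gamma_kin * h1);
      s2 += dt * (-s2 / tauS + (1.0 - s2) * gamma_kin * h2);
      if (s1 < 0.0) s1 = 0.0; else if (s1 > 1.0) s1 = 1.0;
      if (s2 < 0.0) s2 = 0.0; else if (s2 > 1.0) s2 = 1.0;
      if (sigma > 0.0) {
        n1 = ou_step(n1, kdt, amp, rng);
        n2 = ou_step(n2, kdt, amp, rng);
      }
      if (h1 >= thresh || h2 >= thresh) {
        choice = (h1 >= h2) ? 1 : 2;
        rt = s * dt;
        break;
      }
    }
    out(t, 0) = rt;
    out(t, 1) = choice;
  }
  return out;
}

// Noiseless steady state of the N-population reduced recurrent network
// under constant input currents.  Euler integration until max |dS| / dt
// falls below tol (returns rates H) or t_max is reached (last column of the
// return value flags convergence).
// [[Rcpp::export]]
NumericVector cpp_rnm_steady(NumericVector inputs, double jn_same,
                             double jn_diff, double I0, double gamma_kin,
                             double s0, double tauS, double a, double b,
                             double d, double dt, double t_max,
                             double tol) {
  const int n = inputs.size();
  std::vector<double> S(n, s0), dS(n), H(n);
  const int n_max = (int)std::lround(t_max / dt);
  bool converged = false;
  for (int step = 0; step < n_max; ++step) {
    double ssum = 0.0;
    for (int i = 0; i < n; ++i) ssum += S[i];
    double dmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double x = jn_same * S[i] - jn_diff * (ssum - S[i]) + I0 + inputs[i];
      H[i] = ww_H(x, a, b, d);
      if (H[i] < 0.0) H[i] = 0.0;
      dS[i] = -S[i] / tauS + (1.0 - S[i]) * gamma_kin * H[i];
      if (std::fabs(dS[i]) > dmax) dmax = std::fabs(dS[i]);
    }
    if (dmax < tol) { converged = true; break; }
    for (int i = 0; i < n; ++i) {
      S[i] += dt * dS[i];
      if (S[i] < 0.0) S[i] = 0.0; else if (S[i] > 1.0) S[i] = 1.0;
    }
  }
  NumericVector out(n + 1);
  for (int i = 0; i < n; ++i) out[i] = H[i];
  out[n] = converged ? 1.0 : 0.0;
  return out;
}

// Leaky competing accumulator trials (Euler-Maruyama, clamp at zero).
// dx_i = (rho_i - k x_i - beta_inh x_j) dt/tau + sigma sqrt(dt/tau) eta.
// [[Rcpp::export]]
NumericMatrix cpp_lca_trials(int n, double rho1, double rho2, double k,
                             double beta_inh, double sigma, double thresh,
                             double tau, double dt, double cutoff,
                             int seed) {
  NumericMatrix out(n, 2);
  Rng rng((uint64_t)seed);
  const int n_max = (int)std::lround(cutoff / dt);
  const double kdt = dt / tau;
  const double amp = sigma * std::sqrt(dt / tau);
  for (int t = 0; t < n; ++t) {
    double x1 = 0.0, x2 = 0.0;
    double rt = NA_REAL;
    int choice = 0;
    for (int s = 1; s <= n_max; ++s) {
      double d1 = (rho1 - k * x1 - beta_inh * x2) * kdt;
      double d2 = (rho2 - k * x2 - beta_inh * x1) * kdt;
      if (sigma > 0.0) {
        d1 += amp * rng.norm();
        d2 += amp * rng.norm();
      }
      x1 += d1;
      x2 += d2;
      if (x1 < 0.0) x1 = 0.0;
      if (x2 < 0.0) x2 = 0.0;
      if (x1 >= thresh || x2 >= thresh) {
        choice = (x1 >= x2) ? 1 : 2;
        rt = s * dt;
        break;
      }
    }
    out(t, 0) = rt;
    out(t, 1) = choice;
  }
  return out;
}
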