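// Stochastic Heun integration of the chemical Langevin equations of the
// ABA-GA-Integrator germination switch. The inner loop lives here because an
// ensemble is n_seeds independent first-passage simulations of up to
// t_final/dt steps each.
//
// RNG: counter-based per-seed substreams (splitmix64-seeded xoshiro256++,
// Box-Muller normals). Each seed's stream depends only on (master_seed,
// seed index), so ensembles are order-independent and reproducible across
// platforms independently of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (0xD1B54A32D192ED03ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
    have_spare = false;
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {  // standard normal, Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

struct Params {
  double beta_ABA, beta_GA, beta_GA_Z, beta_Z, beta_I;
  double v_ABA, v_GA, v_Z, v_I;
  double theta_ABA_I, theta_GA_I, theta_I_ABA, theta_I_GA;
  double C_ABA_I, C_GA_I, C_I_ABA, C_I_GA;
  double h, V;
};

inline double powh(double x, double h) {
  if (h == 4.0) { double x2 = x * x; return x2 * x2; }
  if (h == 2.0) return x * x;
  return std::pow(x, h);
}

inline double hill_inc(double y, double C, double theta, double h) {
  double r = powh(y / theta, h);
  return C * r / (1.0 + r);
}

inline double hill_dec(double y, double C, double theta, double h) {
  return C / (1.0 + powh(y / theta, h));
}

// production (pos) and degradation (neg) term magnitudes per variable
inline void terms(const Params& p, const double x[4],
                  double aba_exo, double ga_exo,
                  double pos[4], double neg[4]) {
  double f_ABA  = hill_inc(x[2], p.C_ABA_I, p.theta_ABA_I, p.h);
  double g_GA   = hill_dec(x[2], p.C_GA_I, p.theta_GA_I, p.h);
  double f_I    = hill_inc(x[0] + aba_exo, p.C_I_ABA, p.theta_I_ABA, p.h);
  double f_I_GA = hill_inc(x[1] + ga_exo, p.C_I_GA, p.theta_I_GA, p.h);
  pos[0] = p.beta_ABA + f_ABA;                       neg[0] = p.v_ABA * x[0];
  pos[1] = p.beta_GA + p.beta_GA_Z * x[3] + g_GA;    neg[1] = p.v_GA * x[1];
  pos[2] = p.beta_I + f_I;                           neg[2] = (p.v_I + f_I_GA) * x[2];
  pos[3] = p.beta_Z;                                 neg[3] = p.v_Z * x[3];
}

Params unpack(const List& params) {
  Params p;
  p.beta_ABA = params["beta_ABA"]; p.beta_GA = params["beta_GA"];
  p.beta_GA_Z = params["beta_GA_Z"]; p.beta_Z = params["beta_Z"];
  p.beta_I = params["beta_I"];
  p.v_ABA = params["v_ABA"]; p.v_GA = params["v_GA"];
  p.v_Z = params["v_Z"]; p.v_I = params["v_I"];
  p.theta_ABA_I = params["theta_ABA_I"]; p.theta_GA_I = params["theta_GA_I"];
  p.theta_I_ABA = params["theta_I_ABA"]; p.theta_I_GA = params["theta_I_GA"];
  p.C_ABA_I = params["C_ABA_I"]; p.C_GA_I = params["C_GA_I"];
  p.C_I_ABA = params["C_I_ABA"]; p.C_I_GA = params["C_I_GA"];
  p.h = params["h"]; p.V = params["V"];
  return p;
}

// one stochastic Heun step (Ito interpretation): predictor uses drift and
// diffusion at the current state, corrector averages the drift only; the
// same Gaussian increment is reused; absorptive barrier (clamp to 0) after
// both stages.
inline void heun(const Params& p, double x[4], double aba_exo, double ga_exo,
                 double dt, const double dW[4], bool use_noise) {
  double pos[4], neg[4], a0[4], b0[4], xp[4], a1[4];
  double pref = 1.0 / (2.0 * p.V);
  terms(p, x, aba_exo, ga_exo, pos, neg);
  for (int k = 0; k < 4; ++k) {
    a0[k] = pos[k] - neg[k];
    b0[k] = use_noise ? std::sqrt(pref * (pos[k] + neg[k])) : 0.0;
    xp[k] = x[k] + a0[k] * dt + b0[k] * dW[k];
    if (xp[k] < 0.0) xp[k] = 0.0;
  }
  terms(p, xp, aba_exo, ga_exo, pos, neg);
  for (int k = 0; k < 4; ++k) {
    a1[k] = pos[k] - neg[k];
    x[k] += 0.5 * (a0[k] + a1[k]) * dt + b0[k] * dW[k];
    if (x[k] < 0.0) x[k] = 0.0;
  }
}

}  // namespace

// Simulate an ensemble of seeds; returns per-seed germination time (step-end
// convention) or NA when the Integrator never drops below threshold by
// t_final.
// [[Rcpp::export(name = ".simulate_ensemble_cpp")]]
NumericVector simulate_ensemble_cpp(List params, double aba_exo, double ga_exo,
                                    NumericVector init, double dt,
                                    double t_final, double threshold,
                                    int n_seeds, double master_seed,
                                    bool use_noise) {
  Params p = unpack(params);
  if (init.size() != 4) stop("init must have length 4 (ABA, GA, I, Z)");
  long n_steps = (long)std::ceil(t_final / dt - 1e-9);
  NumericVector out(n_seeds, NA_REAL);
  uint64_t master = (uint64_t)(int64_t)master_seed;
  Xoshiro rng;

  for (int i = 0; i < n_seeds; ++i) {
    rng.seed(master, (uint64_t)i);
    double x[4] = {init[0], init[1], init[2], init[3]};
    // the crossing check runs only after full steps: a start below threshold
    // can still escape upward through the first stochastic step
    for (long step = 0; step < n_steps; ++step) {
      double dW[4] = {0, 0, 0, 0};
      if (use_noise) {
        double sdt = std::sqrt(dt);
        for (int k = 0; k < 4; ++k) dW[k] = sdt * rng.norm();
      }
      heun(p, x, aba_exo, ga_exo, dt, dW, use_noise);
      for (int k = 0; k < 4; ++k)
        if (!std::isfinite(x[k]))
          stop("non-finite state component %d at step %ld", k + 1, step + 1);
      if (x[2] < threshold) { out[i] = (step + 1) * dt; break; }
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Record a single trajectory (rows: time points 0..n_steps; cols: t, ABA,
// GA, I, Z). Used for diagnostics and stationary-fluctuation checks.
// [[Rcpp::export(name = ".simulate_trajectory_cpp")]]
NumericMatrix simulate_trajectory_cpp(List params, double aba_exo,
                                      double ga_exo, NumericVector init,
                                      double dt, long n_steps,
                                      double master_seed, bool use_noise,
                                      int stream) {
  Params p = unpack(params);
  if (init.size() != 4) stop("init must have length 4 (ABA, GA, I, Z)");
  NumericMatrix out(n_steps + 1, 5);
  Xoshiro rng;
  rng.seed((uint64_t)(int64_t)master_seed, (uint64_t)stream);
  double x[4] = {init[0], init[1], init[2], init[3]};
  out(0, 0) = 0.0;
  for (int k = 0; k < 4; ++k) out(0, k + 1) = x[k];
  for (long step = 0; step < n_steps; ++step) {
    double dW[4] = {0, 0, 0, 0};
    if (use_noise) {
      double sdt = std::sqrt(dt);
      for (int k = 0; k < 4; ++k) dW[k] = sdt * rng.norm();
    }
    heun(p, x, aba_exo, ga_exo, dt, dW, use_noise);
    out(step + 1, 0) = (step + 1) * dt;
    for (int k = 0; k < 4; ++k) out(step + 1, k + 1) = x[k];
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
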