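// Fixed-step simulator cores: phase-oscillator neuron with prescribed PRC,
// Wang-Buzsaki-style conductance surrogate, and exact Markov channel gating.
// All randomness goes through R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
using namespace Rcpp;

// linear interpolation of z_true sampled on a uniform grid over [0, 1]
static inline double z_interp(const NumericVector& zg, double phi) {
  const int n = zg.size();
  if (phi <= 0.0) return zg[0];
  if (phi >= 1.0) return zg[n - 1];
  double x = phi * (n - 1);
  int i = (int)x;
  if (i >= n - 1) return zg[n - 1];
  double f = x - i;
  return zg[i] * (1.0 - f) + zg[i + 1] * f;
}

// Advance the phase neuron until the next spike (phi crossing 1) or t_stop.
// dphi/dt = f(I_hold) + z_true(phi) * I_pulse(t) + cv * sqrt(f) * xi(t)
// with f(I) = max(f0 + f_slope * I, 0). A square pulse of amplitude
// pulse_amp (pA) is active on [pulse_t, pulse_t + pulse_dur); pass
// pulse_t = NA for none. Returns the (interpolated) spike time, or NA if
// t_stop was reached first, plus the updated state (t, phi).
// [[Rcpp::export]]
List phase_advance_cpp(double t, double phi, double t_stop,
                       double i_hold, double pulse_t, double pulse_amp,
                       double pulse_dur, double f0, double f_slope,
                       double cv, NumericVector z_grid, double dt) {
  RNGScope scope;
  const bool has_pulse = R_finite(pulse_t);
  double t_spike = NA_REAL;
  while (t < t_stop - 1e-15) {
    double step = std::min(dt, t_stop - t);
    double f = f0 + f_slope * i_hold;
    if (f < 0.0) f = 0.0;
    double ip = 0.0;
    if (has_pulse && t >= pulse_t && t < pulse_t + pulse_dur) ip = pulse_amp;
    double drift = f + z_interp(z_grid, phi) * ip;
    double dphi = drift * step;
    if (cv > 0.0 && f > 0.0)
      dphi += cv * std::sqrt(f) * std::sqrt(step) * norm_rand();
    double phi_new = phi + dphi;
    if (phi_new >= 1.0) {
      double frac = (dphi > 0.0) ? (1.0 - phi) / dphi : 1.0;
      if (frac < 0.0) frac = 0.0;
      if (frac > 1.0) frac = 1.0;
      t_spike = t + frac * step;
      phi = phi_new - 1.0;
      t += step;
      break;
    }
    if (phi_new < 0.0) phi_new = 0.0;  // jitter cannot push the phase below 0
    phi = phi_new;
    t += step;
  }
  return List::create(_["t_spike"] = t_spike, _["t"] = t, _["phi"] = phi);
}

// As phase_advance_cpp, but the perturbation current is a sampled trace
// (e.g. an OU stimulus) entering through the PRC, instead of a square pulse.
// stim[i] is the current at stim_t0 + i * stim_dt; zero outside the trace.
// [[Rcpp::export]]
List phase_advance_trace_cpp(double t, double phi, double t_stop,
                             double i_hold, NumericVector stim,
                             double stim_t0, double stim_dt,
                             double f0, double f_slope, double cv,
                             NumericVector z_grid, double dt) {
  RNGScope scope;
  const int ns = stim.size();
  double t_spike = NA_REAL;
  while (t < t_stop - 1e-15) {
    double step = std::min(dt, t_stop - t);
    double f = f0 + f_slope * i_hold;
    if (f < 0.0) f = 0.0;
    double ip = 0.0;
    double x = (t - stim_t0) / stim_dt;
    if (x >= 0.0 && x < ns - 1) {
      int i = (int)x;
      double fr = x - i;
      ip = stim[i] * (1.0 - fr) + stim[i + 1] * fr;
    }
    double drift = f + z_interp(z_grid, phi) * ip;
    double dphi = drift * step;
    if (cv > 0.0 && f > 0.0)
      dphi += cv * std::sqrt(f) * std::sqrt(step) * norm_rand();
    double phi_new = phi + dphi;
    if (phi_new >= 1.0) {
      double frac = (dphi > 0.0) ? (1.0 - phi) / dphi : 1.0;
      if (frac < 0.0) frac = 0.0;
      if (frac > 1.0) frac = 1.0;
      t_spike = t + frac * step;
      phi = phi_new - 1.0;
      t += step;
      break;
    }
    if (phi_new < 0.0) phi_new = 0.0;
    phi = phi_new;
    t += step;
  }
  return List::create(_["t_spike"] = t_spike, _["t"] = t, _["phi"] = phi);
}

// ---- Wang-Buzsaki-style conductance surrogate -----------------------------

struct WBParams {
  double cm, gna, gk, gl, ena, ek, el, phi_temp, area_cm2, i_bias;
};

static WBParams wb_from_list(const List& p) {
  WBParams w;
  w.cm = p["cm"]; w.gna = p["gna"]; w.gk = p["gk"]; w.gl = p["gl"];
  w.ena = p["ena"]; w.ek = p["ek"]; w.el = p["el"];
  w.phi_temp = p["phi_temp"]; w.area_cm2 = p["area_cm2"];
  w.i_bias = p["i_bias"];
  return w;
}

static inline double safe_exp_ratio(double x, double scale) {
  // x / (1 - exp(-x/scale)) with the removable singularity at x = 0
  double r = x / scale;
  if (std::fabs(r) < 1e-6) return scale * (1.0 + r / 2.0);
  return x / (1.0 - std::exp(-r));
}

// derivatives; v in mV, time in ms
static inline void wb_deriv(const WBParams& w, double v, double h, double n,
                            double i_dens, double eta_k,
                            double& dv, double& dh, double& dn) {
  double am = 0.1 * safe_exp_ratio(v + 35.0, 10.0);
  double bm = 4.0 * std::exp(-(v + 60.0) / 18.0);
  double minf = am / (am + bm);
  double ah = 0.07 * std::exp(-(v + 58.0) / 20.0);
  double bh = 1.0 / (std::exp(-0.1 * (v + 28.0)) + 1.0);
  double an = 0.01 * safe_exp_ratio(v + 34.0, 10.0);
  double bn = 0.125 * std::exp(-(v + 44.0) / 80.0);
  double po_k = n * n * n * n + eta_k;  // open fraction + channel-noise term
  if (po_k < 0.0) po_k = 0.0;
  double ina = w.gna * minf * minf * minf * h * (v - w.ena);
  double ik = w.gk * po_k * (v - w.ek);
  double il = w.gl * (v - w.el);
  dv = (-ina - ik - il + i_dens + w.i_bias) / w.cm;  // mV/ms
  dh = w.phi_temp * (ah * (1.0 - h) - bh * h);
  dn = w.phi_temp * (an * (1.0 - n) - bn * n);
}

// Advance the conductance neuron until the next spike (upward crossing of
// 0 mV) or t_stop (seconds). state = (V, h, n, eta_1..eta_m) where the
// eta_i are OU channel-noise terms added to the K open fraction
// (taus in seconds, sigmas dimensionless; empty vectors for none).
// RK2 (midpoint) for the deterministic part, exact OU update for the noise.
// [[Rcpp::export]]
List cond_advance_cpp(NumericVector state, double t, double t_stop,
                      double i_hold, double pulse_t, double pulse_amp,
                      double pulse_dur, List params,
                      NumericVector noise_tau, NumericVector noise_sigma,
                      double dt, double i_noise_pA = 0.0,
                      bool record = false) {
  RNGScope scope;
  WBParams w = wb_from_list(params);
  const bool has_pulse = R_finite(pulse_t);
  const int m = noise_tau.size();
  double v = state[0], h = state[1], n = state[2];
  std::vector<double> eta(m);
  for (int i = 0; i < m; ++i) eta[i] = state[3 + i];
  std::vector<double> rho(m), sd(m);
  for (int i = 0; i < m; ++i) {
    rho[i] = std::exp(-dt / noise_tau[i]);
    sd[i] = noise_sigma[i] * std::sqrt(1.0 - rho[i] * rho[i]);
  }
  int n_rec = record ? (int)std::ceil((t_stop - t) / dt) + 2 : 0;
  NumericVector rec_t(n_rec), rec_v(n_rec);
  int ir = 0;
  double t_spike = NA_REAL;
  const double dt_ms = dt * 1e3;
  while (t < t_stop - 1e-15) {
    double ip = 0.0;
    if (has_pulse && t >= pulse_t && t < pulse_t + pulse_dur) ip = pulse_amp;
    // delta-correlated noisy current: fresh draw per step, SD in pA at
    // the integration step
    double i_white = (i_noise_pA > 0.0) ? i_noise_pA * norm_rand() : 0.0;
    // pA over the membrane area -> uA/cm^2 (1 pA = 1e-6 uA)
    double i_dens = (i_hold + ip + i_white) * 1e-6 / w.area_cm2;
    double eta_sum = 0.0;
    for (int i = 0; i < m; ++i) eta_sum += eta[i];
    double dv1, dh1, dn1;
    wb_deriv(w, v, h, n, i_dens, eta_sum, dv1, dh1, dn1);
    double vm = v + 0.5 * dt_ms * dv1;
    double hm = h + 0.5 * dt_ms * dh1;
    double nm = n + 0.5 * dt_ms * dn1;
    double dv2, dh2, dn2;
    wb_deriv(w, vm, hm, nm, i_dens, eta_sum, dv2, dh2, dn2);
    double v_new = v + dt_ms * dv2;
    double h_new = h + dt_ms * dh2;
    double n_new = n + dt_ms * dn2;
    if (!R_finite(v_new) || std::fabs(v_new) > 500.0)
      stop("conductance simulation diverged (V = %f mV at t = %f s)", v_new, t);
    for (int i = 0; i < m; ++i)
      eta[i] = eta[i] * rho[i] + sd[i] * norm_rand();
    bool crossed = (v < 0.0 && v_new >= 0.0);
    if (record && ir < n_rec) { rec_t[ir] = t; rec_v[ir] = v; ++ir; }
    double t_new = t + dt;
    if (crossed && !R_finite(t_spike)) {
      double frac = (v_new > v) ? (0.0 - v) / (v_new - v) : 1.0;
      t_spike = t + frac * dt;
      v = v_new; h = h_new; n = n_new; t = t_new;
      break;
    }
    v = v_new; h = h_new; n = n_new; t = t_new;
  }
  NumericVector out_state(3 + m);
  out_state[0] = v; out_state[1] = h; out_state[2] = n;
  for (int i = 0; i < m; ++i) out_state[3 + i] = eta[i];
  List out = List::create(_["t_spike"] = t_spike, _["t"] = t,
                          _["state"] = out_state);
  if (record) {
    out["rec_t"] = NumericVector(rec_t.begin(), rec_t.begin() + ir);
    out["rec_v"] = NumericVector(rec_v.begin(), rec_v.begin() + ir);
  }
  return out;
}

// ---- exact Markov channel population --------------------------------------

// Population simulation of n_channels independent channels with generator
// rates[i][j] = transition rate from state i to state j (1/s). Per step,
// channels leave state i with probability rate*dt (first-order), and the
// open fraction (sum over open states) is recorded every keep_every steps.
// [[Rcpp::export]]
NumericVector markov_population_cpp(NumericMatrix rates, IntegerVector open,
                                    IntegerVector counts0, int n_steps,
                                    double dt, int keep_every) {
  RNGScope scope;
  const int ns = rates.nrow();
  if (rates.ncol() != ns) stop("rate matrix must be square");
  double max_out = 0.0;
  for (int i = 0; i < ns; ++i) {
    double tot = 0.0;
    for (int j = 0; j < ns; ++j) if (j != i) tot += rates(i, j);
    if (tot > max_out) max_out = tot;
  }
  if (max_out * dt > 0.1)
    stop("dt * max total rate = %f > 0.1; decrease dt", max_out * dt);
  long n_channels = 0;
  std::vector<int> counts(ns);
  for (int i = 0; i < ns; ++i) { counts[i] = counts0[i]; n_channels += counts0[i]; }
  const int n_keep = n_steps / keep_every;
  NumericVector out(n_keep);
  std::vector<double> p(ns);
  std::vector<int> moved(ns);
  int ik = 0;
  for (int step = 0; step < n_steps; ++step) {
    std::vector<int> next(ns, 0);
    for (int i = 0; i < ns; ++i) {
      int ni = counts[i];
      if (ni == 0) continue;
      // multinomial split of the ni channels in state i over destinations
      double stay = 1.0;
      for (int j = 0; j < ns; ++j) {
        p[j] = (j == i) ? 0.0 : rates(i, j) * dt;
        if (j != i) stay -= p[j];
      }
      p[i] = stay;
      rmultinom(ni, p.data(), ns, moved.data());
      for (int j = 0; j < ns; ++j) next[j] += moved[j];
    }
    counts = next;
    if ((step + 1) % keep_every == 0 && ik < n_keep) {
      long n_open = 0;
      for (int j = 0; j < ns; ++j) if (open[j]) n_open += counts[j];
      out[ik++] = (double)n_open / (double)n_channels;
    }
  }
  return out;
}
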