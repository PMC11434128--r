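#ifndef SOMNOTC_KINETICS_H
#define SOMNOTC_KINETICS_H

#include <cmath>
#include <cstdint>

namespace somnotc {

// ---- generic helpers --------------------------------------------------

// Boltzmann steady state 1/(1+exp(-(V-Vh)/k)); sign of k sets direction.
inline double sigmoid_inf(double v, double vhalf, double slope) {
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / slope));
}

// x*(exp guard): a*(v-th)/(1-exp(-(v-th)/q)) with removable singularity at th.
inline double vtrap(double x, double q) {
  // x/(1 - exp(-x/q)); limit q as x -> 0
  if (std::fabs(x / q) < 1e-6) return q * (1.0 + 0.5 * x / q);
  return x / (1.0 - std::exp(-x / q));
}

// exponential relaxation of a gate over one step
inline double exp_gate(double x, double xinf, double tau, double dt) {
  return xinf + (x - xinf) * std::exp(-dt / tau);
}

// Nernst potential for Ca2+ (valence 2), mV
inline double nernst_eca(double ca_in, double ca_out, double temp_k) {
  const double RF = 8.31446261815324 / 96485.33212; // V per K
  return 1000.0 * RF * temp_k / 2.0 * std::log(ca_out / ca_in);
}

// ---- fast spiking currents (Traub-style rates, shifted by vtraub) ------

struct Rates { double am, bm, ah, bh, an, bn; };

inline Rates traub_rates(double v, double vtraub) {
  double v2 = v - vtraub; // vtraub default -63 mV
  Rates r;
  // a*(x)/(exp(x/q)-1) written via vtrap(-x, q) = x/(exp(x/q)-1)
  r.am = 0.32 * vtrap(v2 - 13.0, 4.0);
  r.bm = 0.28 * vtrap(40.0 - v2, 5.0);
  r.ah = 0.128 * std::exp((17.0 - v2) / 18.0);
  r.bh = 4.0 / (1.0 + std::exp((40.0 - v2) / 5.0));
  r.an = 0.032 * vtrap(v2 - 15.0, 5.0);
  r.bn = 0.5 * std::exp((10.0 - v2) / 40.0);
  return r;
}

// ---- low-threshold (T-type) calcium current ----------------------------

// thalamocortical relay variant
inline void it_tc(double v, double phi_m, double phi_h,
                  double &minf, double &mtau, double &hinf, double &htau) {
  minf = sigmoid_inf(v, -59.0, 6.2);
  hinf = sigmoid_inf(v, -83.0, -4.0);
  mtau = (0.612 + 1.0 / (std::exp(-(v + 132.0) / 16.7) +
                         std::exp((v + 16.8) / 18.2))) / phi_m;
  htau = (30.8 + (211.4 + std::exp((v + 113.2) / 5.0)) /
                     (1.0 + std::exp((v + 84.0) / 3.2))) / phi_h;
}

// reticular variant
inline void it_re(double v, double phi_m, double phi_h,
                  double &minf, double &mtau, double &hinf, double &htau) {
  minf = sigmoid_inf(v, -52.0, 7.4);
  hinf = sigmoid_inf(v, -80.0, -5.0);
  mtau = (3.0 + 1.0 / (std::exp((v + 27.0) / 10.0) +
                       std::exp(-(v + 102.0) / 15.0))) / phi_m;
  htau = (85.0 + 1.0 / (std::exp((v + 48.0) / 4.0) +
                        std::exp(-(v + 407.0) / 50.0))) / phi_h;
}

// ---- hyperpolarization-activated current with Ca regulation ------------
// states: open O, locked-open OL (closed C = 1-O-OL), bound messenger P1.

struct IhPar { double k1, k2, k3, k4, ginc, eh; };

inline void ih_voltage_gate(double v, double &hinf, double &taus) {
  hinf = sigmoid_inf(v, -75.0, -5.5);
  taus = 20.0 + 1000.0 / (std::exp((v + 71.5) / 14.2) +
                          std::exp(-(v + 89.0) / 11.6));
}

inline void ih_step(double v, double ca, double dt, const IhPar &p,
                    double &O, double &OL, double &P1) {
  double hinf, taus;
  ih_voltage_gate(v, hinf, taus);
  double alpha = hinf / taus, beta = (1.0 - hinf) / taus;
  double C = 1.0 - O - OL;
  double ca4 = ca * ca * ca * ca;
  double k1ca = p.k1 * ca4;
  // messenger binding is linear in P1: exact exponential update
  double rsum = k1ca + p.k2;
  double p1inf = (rsum > 0) ? k1ca / rsum : P1;
  double P1n = p1inf + (P1 - p1inf) * std::exp(-dt * rsum);
  // O/OL forward Euler (rates are slow relative to dt)
  double dO = alpha * C - beta * O - p.k3 * P1 * O + p.k4 * OL;
  double dOL = p.k3 * P1 * O - p.k4 * OL;
  O += dt * dO;
  OL += dt * dOL;
  P1 = P1n;
}

// ---- cortical dendritic currents ---------------------------------------

// muscarinic K current (single gate); q is the temperature factor
inline void km_rates(double v, double q, double &a, double &b) {
  a = q * 1e-3 * vtrap(v + 30.0, 9.0);
  b = q * 1e-3 * vtrap(-(v + 30.0), 9.0);
}

// Ca-dependent K current: alpha = kf*Ca, beta constant
inline void kca_rates(double ca, double kf, double bk, double &a, double &b) {
  a = kf * ca;
  b = bk;
}

// persistent sodium: fast sigmoid activation
inline double nap_minf(double v) { return sigmoid_inf(v, -42.0, 5.0); }

// high-voltage-activated Ca current, m^2 h
inline void hva_rates(double v, double q,
                      double &am, double &bm, double &ah, double &bh) {
  am = q * 0.055 * vtrap(v + 27.0, 3.8);
  bm = q * 0.94 * std::exp((-75.0 - v) / 17.0);
  ah = q * 4.57e-4 * std::exp((-13.0 - v) / 50.0);
  bh = q * 6.5e-3 / (std::exp((-15.0 - v) / 28.0) + 1.0);
}

// ---- synapses ----------------------------------------------------------

// short-term depression resource after an interval dt since last spike
inline double depression_update(double e_prev, double dt, double u, double tau_d) {
  return 1.0 - (1.0 - e_prev * (1.0 - u)) * std::exp(-dt / tau_d);
}

// NMDA magnesium block
inline double nmda_mg_block(double v, double mg) {
  return 1.0 / (1.0 + std::exp(-0.062 * v) * mg / 3.57);
}

// first-order transmitter-gated channel, exact step for constant T
inline double kinetic_open_step(double o, double T, double alpha, double beta,
                                double dt) {
  double r = alpha * T + beta;
  if (r <= 0) return o;
  double oinf = alpha * T / r;
  return oinf + (o - oinf) * std::exp(-dt * r);
}

// ---- counter-based RNG (splitmix64) ------------------------------------

inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// uniform in (0,1), deterministic in (seed, stream, counter)
inline double u01(std::uint64_t seed, std::uint64_t stream, std::uint64_t ctr) {
  std::uint64_t z = splitmix64(seed ^ splitmix64(stream ^ splitmix64(ctr)));
  return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// next miniature-release interval under hazard r(s) = rmax*(1-exp(-s/tau)),
// s measured from t_ref (last presynaptic spike or last mini); inverts the
// integrated hazard by Newton iteration.
inline double mini_interval(double u, double rmax, double tau) {
  if (rmax <= 0) return INFINITY;
  double x = -std::log(u); // target integrated hazard
  if (tau <= 0) return x / rmax;
  double T = x / rmax + tau; // start beyond the refractory shoulder
  for (int i = 0; i < 60; ++i) {
    double ex = std::exp(-T / tau);
    double f = rmax * (T - tau * (1.0 - ex)) - x;
    double fp = rmax * (1.0 - ex);
    if (fp < 1e-14) { T += tau; continue; }
    double step = f / fp;
    T -= step;
    if (T < 0) T = 1e-6;
    if (std::fabs(step) < 1e-10 * (1.0 + T)) break;
  }
  return T;
}

} // namespace somnotc

#endif
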