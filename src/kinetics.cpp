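#include <Rcpp.h>
#include "kinetics.h"

using namespace Rcpp;
using namespace somnotc;

//' Boltzmann steady-state activation
//'
//' Canonical sigmoid used by every voltage-gated steady state in the model:
//' \code{1/(1 + exp(-(v - v_half)/slope))}. A negative slope yields an
//' inactivation-type (decreasing) curve.
//'
//' @param v Membrane potential (mV). Vectorised.
//' @param v_half Half-activation voltage (mV).
//' @param slope Slope factor (mV); must be non-zero.
//' @return Open fraction strictly between 0 and 1.
//' @examples
//' sigmoid_inf(-59, -59, 6.2) # 0.5 at the half-activation voltage
//' @export
// [[Rcpp::export]]
NumericVector sigmoid_inf(NumericVector v, double v_half, double slope) {
  if (slope == 0) stop("slope must be non-zero");
  NumericVector out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i)
    out[i] = somnotc::sigmoid_inf(v[i], v_half, slope);
  return out;
}

//' Low-threshold calcium current kinetics, thalamocortical relay variant
//'
//' Steady states and time constants of the T-type current that supports
//' post-inhibitory rebound bursting in relay cells. Activation
//' \code{m_inf = sigmoid_inf(v, -59, 6.2)}, inactivation
//' \code{h_inf = sigmoid_inf(v, -83, -4)}; time constants are the standard
//' biexponential forms divided by the temperature factors. The current is
//' \code{g_T * m^2 * h * (v - E_Ca)}.
//'
//' @param v Membrane potential (mV).
//' @param phi_m,phi_h Temperature acceleration factors (dimensionless).
//' @return A list with \code{m_inf}, \code{tau_m}, \code{h_inf}, \code{tau_h}
//'   (time constants in ms).
//' @export
// [[Rcpp::export]]
List it_tc_kinetics(double v, double phi_m = 6.96, double phi_h = 3.74) {
  double minf, mtau, hinf, htau;
  it_tc(v, phi_m, phi_h, minf, mtau, hinf, htau);
  return List::create(_["m_inf"] = minf, _["tau_m"] = mtau,
                      _["h_inf"] = hinf, _["tau_h"] = htau);
}

//' Low-threshold calcium current kinetics, reticular variant
//'
//' Reticular-nucleus variant of the T-type current
//' (\code{m_inf = sigmoid_inf(v, -52, 7.4)},
//' \code{h_inf = sigmoid_inf(v, -80, -5)}).
//'
//' @inheritParams it_tc_kinetics
//' @return A list with \code{m_inf}, \code{tau_m}, \code{h_inf}, \code{tau_h}.
//' @export
// [[Rcpp::export]]
List it_re_kinetics(double v, double phi_m = 6.96, double phi_h = 3.74) {
  double minf, mtau, hinf, htau;
  it_re(v, phi_m, phi_h, minf, mtau, hinf, htau);
  return List::create(_["m_inf"] = minf, _["tau_m"] = mtau,
                      _["h_inf"] = hinf, _["tau_h"] = htau);
}

//' One step of the calcium-regulated h-current scheme
//'
//' Four-process kinetic scheme of the hyperpolarization-activated cation
//' current of relay cells: voltage gating between closed and open
//' (steady state \code{sigmoid_inf(v, -75, -5.5)}, time constant
//' \code{20 + 1000/(exp((v+71.5)/14.2) + exp(-(v+89)/11.6))} ms), calcium
//' binding of a messenger (forward rate \code{k1*Ca^4}), and locking of open
//' channels by the bound messenger into a locked-open state with conductance
//' gain \code{g_inc}. Current: \code{g_h*(O + g_inc*OL)*(v - e_h)}.
//'
//' @param state Named list or vector with elements \code{O}, \code{OL},
//'   \code{P1} (fractions).
//' @param v Membrane potential (mV).
//' @param ca Intracellular calcium (mM).
//' @param dt Time step (ms), must be positive.
//' @param k1,k2 Messenger binding/unbinding rates (mM^-4 ms^-1, ms^-1).
//' @param k3,k4 Locking/unlocking rates (ms^-1).
//' @return Updated list with \code{O}, \code{OL}, \code{P1}.
//' @export
// [[Rcpp::export]]
List ih_regulated_step(List state, double v, double ca, double dt,
                       double k1 = 2.5e7, double k2 = 4e-4,
                       double k3 = 0.1, double k4 = 1e-3) {
  if (dt <= 0) stop("dt must be positive");
  double O = as<double>(state["O"]);
  double OL = as<double>(state["OL"]);
  double P1 = as<double>(state["P1"]);
  IhPar p; p.k1 = k1; p.k2 = k2; p.k3 = k3; p.k4 = k4; p.ginc = 2; p.eh = -40;
  ih_step(v, ca, dt, p, O, OL, P1);
  return List::create(_["O"] = O, _["OL"] = OL, _["P1"] = P1);
}

//' Cortical dendritic current kinetics
//'
//' Rate terms of the dendritic current set of the two-compartment cortical
//' cells: muscarinic K current (I_Km, alpha/beta with a removable
//' singularity at -30 mV evaluated by limit), calcium-dependent K current
//' (I_KCa, alpha proportional to [Ca]), persistent sodium (I_NaP, fast
//' sigmoid activation), and high-voltage-activated calcium (I_HVA, m^2 h).
//'
//' @param v Membrane potential (mV).
//' @param ca Intracellular calcium (mM), positive.
//' @param q Temperature factor applied to I_Km and I_HVA rates.
//' @param kf_kca Forward rate constant of I_KCa (mM^-1 ms^-1).
//' @param beta_kca Backward rate of I_KCa (ms^-1).
//' @return Nested list with per-current alpha/beta (or \code{m_inf}) terms.
//' @export
// [[Rcpp::export]]
List km_kca_nap_hva_kinetics(double v, double ca, double q = 2.95,
                             double kf_kca = 5.0, double beta_kca = 0.01) {
  double akm, bkm, akca, bkca, am, bm, ah, bh;
  km_rates(v, q, akm, bkm);
  kca_rates(ca, kf_kca, beta_kca, akca, bkca);
  hva_rates(v, q, am, bm, ah, bh);
  return List::create(
      _["km"] = List::create(_["alpha"] = akm, _["beta"] = bkm),
      _["kca"] = List::create(_["alpha"] = akca, _["beta"] = bkca),
      _["nap"] = List::create(_["m_inf"] = nap_minf(v)),
      _["hva"] = List::create(_["alpha_m"] = am, _["beta_m"] = bm,
                              _["alpha_h"] = ah, _["beta_h"] = bh));
}

//' Fast spiking-current rate functions
//'
//' Traub-style alpha/beta rates for the transient sodium (m^3 h) and delayed
//' rectifier potassium (n^4) currents, with voltages measured relative to a
//' configurable shift \code{vtraub}.
//'
//' @param v Membrane potential (mV).
//' @param vtraub Rate-function voltage shift (mV).
//' @return List with \code{am, bm, ah, bh, an, bn} (ms^-1).
//' @export
// [[Rcpp::export]]
List na_k_rates(double v, double vtraub = -63.0) {
  Rates r = traub_rates(v, vtraub);
  return List::create(_["am"] = r.am, _["bm"] = r.bm, _["ah"] = r.ah,
                      _["bh"] = r.bh, _["an"] = r.an, _["bn"] = r.bn);
}

//' One step of intracellular calcium dynamics
//'
//' First-order pool: \code{d\[Ca\]/dt = -k*I_Ca + (rest - \[Ca\])/tau},
//' advanced with the exact exponential update (the equation is linear in
//' [Ca] for a constant current) and clamped positive.
//'
//' @param ca Current concentration (mM).
//' @param i_ca Calcium current density (uA/cm^2; negative = inward).
//' @param dt Time step (ms), positive.
//' @param ca_rest Resting concentration (mM).
//' @param tau Decay time constant (ms).
//' @param k Influx factor (mM cm^2 / (ms uA)).
//' @return Updated concentration (mM).
//' @export
// [[Rcpp::export]]
double update_calcium(double ca, double i_ca, double dt,
                      double ca_rest = 2.4e-4, double tau = 5.0,
                      double k = 5.1819e-5) {
  if (dt <= 0) stop("dt must be positive");
  double cinf = ca_rest - k * tau * i_ca;
  double out = cinf + (ca - cinf) * std::exp(-dt / tau);
  return out > 1e-8 ? out : 1e-8;
}

//' Calcium reversal potential (Nernst)
//'
//' @param ca_in Intracellular concentration (mM), positive.
//' @param ca_out Extracellular concentration (mM), positive.
//' @param temp Absolute temperature (K).
//' @return Reversal potential (mV).
//' @examples
//' nernst_eca(2.4e-4, 2, 309.15) # ~ +120 mV
//' @export
// [[Rcpp::export]]
double nernst_eca(double ca_in, double ca_out, double temp = 309.15) {
  if (ca_in <= 0 || ca_out <= 0) stop("concentrations must be positive");
  return somnotc::nernst_eca(ca_in, ca_out, temp);
}

//' Short-term depression resource update
//'
//' Resource available at a presynaptic spike arriving \code{dt} ms after the
//' previous one: \code{1 - (1 - E*(1-U))*exp(-dt/tau_d)}. The effective
//' synaptic weight is the base weight times the returned resource.
//'
//' @param e_prev Resource at the previous spike, in (0, 1].
//' @param dt Inter-spike interval (ms), non-negative.
//' @param u Use fraction per spike, in [0, 1).
//' @param tau_d Recovery time constant (ms), positive.
//' @return Updated resource fraction.
//' @export
// [[Rcpp::export]]
double depression_update(double e_prev, double dt, double u, double tau_d) {
  if (dt < 0) stop("dt must be non-negative");
  return somnotc::depression_update(e_prev, dt, u, tau_d);
}

//' One step of a first-order transmitter-gated channel
//'
//' \code{dO/dt = alpha*T*(1-O) - beta*O} advanced with the exact exponential
//' solution for transmitter concentration \code{T} held constant over the
//' step. Used by the AMPA, NMDA and GABA-A receptor models.
//'
//' @param o Open fraction.
//' @param T Transmitter concentration (mM), non-negative.
//' @param alpha Binding rate (mM^-1 ms^-1).
//' @param beta Unbinding rate (ms^-1).
//' @param dt Time step (ms), positive.
//' @return Updated open fraction in \[0, 1\].
//' @export
// [[Rcpp::export]]
double kinetic_open_step(double o, double T, double alpha, double beta,
                         double dt) {
  if (dt <= 0) stop("dt must be positive");
  if (T < 0) stop("T must be non-negative");
  return somnotc::kinetic_open_step(o, T, alpha, beta, dt);
}

//' NMDA magnesium block
//'
//' Voltage-dependent relief of the magnesium block:
//' \code{1/(1 + exp(-0.062*v)*mg/3.57)}; monotone increasing in voltage.
//'
//' @param v Membrane potential (mV). Vectorised.
//' @param mg Extracellular magnesium (mM).
//' @return Unblocked fraction in (0, 1).
//' @export
// [[Rcpp::export]]
NumericVector nmda_mg_block(NumericVector v, double mg = 1.0) {
  NumericVector out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i)
    out[i] = somnotc::nmda_mg_block(v[i], mg);
  return out;
}

//' One step of the second-messenger GABA-B scheme
//'
//' Activated receptor R and G-protein concentration G:
//' \code{dR/dt = K1*T*(1-R) - K2*R}, \code{dG/dt = K3*R - K4*G}. The
//' potassium current activation is \code{G^4/(G^4 + Kd)}.
//'
//' @param state Named list or vector with \code{R} and \code{G}.
//' @param T Transmitter concentration (mM).
//' @param dt Time step (ms), positive.
//' @param K1,K2,K3,K4 Kinetic constants (mM^-1 ms^-1 and ms^-1).
//' @return Updated list with \code{R} and \code{G}.
//' @export
// [[Rcpp::export]]
List gabab_step(List state, double T, double dt, double K1 = 0.52,
                double K2 = 0.0013, double K3 = 0.098, double K4 = 0.033) {
  if (dt <= 0) stop("dt must be positive");
  double R = as<double>(state["R"]);
  double G = as<double>(state["G"]);
  // R is linear for constant T: exact update; G linear given R: exact update
  double rr = K1 * T + K2;
  double rinf = (rr > 0) ? K1 * T / rr : R;
  double Rn = rinf + (R - rinf) * std::exp(-dt * rr);
  double ginf = K3 * R / K4;
  double Gn = ginf + (G - ginf) * std::exp(-dt * K4);
  return List::create(_["R"] = Rn, _["G"] = Gn);
}

//' Transmitter concentration from a pulse train
//'
//' Each presynaptic spike releases a rectangular transmitter pulse of the
//' given amplitude and duration; overlapping pulses saturate at the
//' amplitude (concentrations do not stack).
//'
//' @param spike_times Presynaptic spike times (ms).
//' @param t Evaluation time (ms).
//' @param amplitude Pulse amplitude (mM).
//' @param duration Pulse duration (ms), positive.
//' @return Concentration at \code{t} (mM).
//' @export
// [[Rcpp::export]]
double transmitter_pulse(NumericVector spike_times, double t,
                         double amplitude = 0.5, double duration = 0.3) {
  if (duration <= 0) stop("duration must be positive");
  for (R_xlen_t i = 0; i < spike_times.size(); ++i) {
    double s = t - spike_times[i];
    if (s >= 0 && s < duration) return amplitude;
  }
  return 0.0;
}

//' Next miniature-release time
//'
//' Draws the next spontaneous miniature-EPSP time of a connection from a
//' renewal process whose hazard rises from zero after the reference event
//' (the last presynaptic spike or previous mini) and saturates at
//' \code{rate_max}: \code{r(s) = rate_max*(1 - exp(-s/tau_rise))}. The draw
//' is a pure function of (seed, stream, counter), so runs are reproducible
//' and independent connections have independent substreams.
//'
//' @param seed Integer seed of the run.
//' @param stream Connection substream identifier (non-negative integer).
//' @param counter Draw counter for the connection (non-negative integer).
//' @param t_ref Reference time (ms) the hazard is measured from.
//' @param rate_max Saturated rate (ms^-1); zero disables minis.
//' @param tau_rise Hazard rise time constant (ms).
//' @return Absolute time (ms) of the next mini; \code{Inf} if disabled.
//' @export
// [[Rcpp::export]]
double mini_next_time(double seed, double stream, double counter,
                      double t_ref, double rate_max, double tau_rise) {
  if (rate_max <= 0) return R_PosInf;
  double u = u01((std::uint64_t)seed, (std::uint64_t)stream,
                 (std::uint64_t)counter);
  return t_ref + mini_interval(u, rate_max, tau_rise);
}
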