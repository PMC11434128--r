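// Network integration engine: fixed-step semi-implicit update of all cells,
// exact exponential gating updates, kinetic synapses with depression and
// miniature events, scheduled neuromodulation, and trace/LFP capture.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "kinetics.h"

using namespace Rcpp;
using namespace somnotc;

namespace {

// state-matrix column layouts
enum CxCol { cVS, cVD, cMS, cHS, cNS, cMD, cHD, cMKM, cMKCA, cMHVA, cHHVA,
             cCA, cLS, CX_NCOL };
enum TcCol { tV, tM, tH, tN, tMT, tHT, tO, tOL, tP1, tCA, tLS, TC_NCOL };
enum ReCol { rV, rM, rH, rN, rMT, rHT, rCA, rLS, RE_NCOL };

struct PopPar {
  int n = 0, ncomp = 1;
  double area_s = 0, area_d = 0, cm = 1, gc = 0; // gc in uS
  double gna_s = 0, gk_s = 0, gnap_s = 0;
  double gna_d = 0, gnap_d = 0, gkm = 0, gkca = 0, ghva = 0;
  double gna = 0, gk = 0, gt = 0, gh = 0;
  double gkl = 0, gl = 0, el = -70, ek = -95, ena = 50, eh = -40;
  double vtraub = -63, vinit = -68;
  double ca_rest = 2.4e-4, ca_tau = 5, ca_k = 5.1819e-5, ca_out = 2,
         temp = 309.15;
  double kf_kca = 5, b_kca = 0.01, q = 2.95;
  double phi_m = 6.96, phi_h = 3.74;
  double k1 = 2.5e7, k2 = 4e-4, k3 = 0.1, k4 = 1e-3, ginc = 2;
  double kappa_ach = 0, kappa_ha = 0;
};

double getd(const List &l, const char *nm) {
  if (!l.containsElementNamed(nm))
    stop("engine parameter list missing field '%s'", nm);
  return as<double>(l[nm]);
}

PopPar read_pop(const List &l) {
  PopPar p;
  p.n = (int)getd(l, "n");
  p.ncomp = (int)getd(l, "ncomp");
  p.area_s = getd(l, "area_s"); p.area_d = getd(l, "area_d");
  p.cm = getd(l, "cm"); p.gc = getd(l, "gc");
  p.gna_s = getd(l, "gna_s"); p.gk_s = getd(l, "gk_s");
  p.gnap_s = getd(l, "gnap_s");
  p.gna_d = getd(l, "gna_d"); p.gnap_d = getd(l, "gnap_d");
  p.gkm = getd(l, "gkm"); p.gkca = getd(l, "gkca"); p.ghva = getd(l, "ghva");
  p.gna = getd(l, "gna"); p.gk = getd(l, "gk"); p.gt = getd(l, "gt");
  p.gh = getd(l, "gh");
  p.gkl = getd(l, "gkl"); p.gl = getd(l, "gl");
  p.el = getd(l, "el"); p.ek = getd(l, "ek"); p.ena = getd(l, "ena");
  p.eh = getd(l, "eh");
  p.vtraub = getd(l, "vtraub"); p.vinit = getd(l, "vinit");
  p.ca_rest = getd(l, "ca_rest"); p.ca_tau = getd(l, "ca_tau");
  p.ca_k = getd(l, "ca_k"); p.ca_out = getd(l, "ca_out");
  p.temp = getd(l, "temp");
  p.kf_kca = getd(l, "kf_kca"); p.b_kca = getd(l, "b_kca");
  p.q = getd(l, "q");
  p.phi_m = getd(l, "phi_m"); p.phi_h = getd(l, "phi_h");
  p.k1 = getd(l, "k1"); p.k2 = getd(l, "k2"); p.k3 = getd(l, "k3");
  p.k4 = getd(l, "k4"); p.ginc = getd(l, "ginc");
  p.kappa_ach = getd(l, "kappa_ach"); p.kappa_ha = getd(l, "kappa_ha");
  return p;
}

struct Proj {
  int sp, tp, recep, comp; // recep: 0 AMPA(+NMDA), 1 GABAA, 2 GABAB
  std::vector<int> pre, post;
  std::vector<double> w, wn;
  double erev, alpha, beta, alpha_n, beta_n;
  double K1, K2, K3, K4, Kd;
  double tmax, tdur, delay, U, tau_d;
  bool dep, mod_ampa, mod_gaba, minis;
  double mini_amp, mini_rate, mini_tau;
  double stream0;
  // CSR from presynaptic cell to edge indices
  std::vector<int> csr_off, csr_edge;
  // precomputed decay factors
  double don, oinf_on, doff;           // main receptor
  double don_n, oinf_on_n, doff_n;     // NMDA
  double dron, rinf_on, droff, dgoff;  // GABA-B
};

Proj read_proj(const List &l, int n_pre) {
  Proj p;
  p.sp = (int)getd(l, "sp"); p.tp = (int)getd(l, "tp");
  p.recep = (int)getd(l, "recep"); p.comp = (int)getd(l, "comp");
  p.pre = as<std::vector<int> >(l["pre"]);
  p.post = as<std::vector<int> >(l["post"]);
  p.w = as<std::vector<double> >(l["w"]);
  p.wn = as<std::vector<double> >(l["wn"]);
  p.erev = getd(l, "erev");
  p.alpha = getd(l, "alpha"); p.beta = getd(l, "beta");
  p.alpha_n = getd(l, "alpha_n"); p.beta_n = getd(l, "beta_n");
  p.K1 = getd(l, "K1"); p.K2 = getd(l, "K2"); p.K3 = getd(l, "K3");
  p.K4 = getd(l, "K4"); p.Kd = getd(l, "Kd");
  p.tmax = getd(l, "tmax"); p.tdur = getd(l, "tdur");
  p.delay = getd(l, "delay");
  p.U = getd(l, "U"); p.tau_d = getd(l, "tau_d");
  p.dep = getd(l, "dep") != 0;
  p.mod_ampa = getd(l, "mod_ampa") != 0;
  p.mod_gaba = getd(l, "mod_gaba") != 0;
  p.minis = getd(l, "minis") != 0;
  p.mini_amp = getd(l, "mini_amp"); p.mini_rate = getd(l, "mini_rate");
  p.mini_tau = getd(l, "mini_tau");
  p.stream0 = getd(l, "stream0");
  // CSR
  int ne = (int)p.pre.size();
  p.csr_off.assign(n_pre + 1, 0);
  for (int e = 0; e < ne; ++e) p.csr_off[p.pre[e] + 1]++;
  for (int i = 0; i < n_pre; ++i) p.csr_off[i + 1] += p.csr_off[i];
  p.csr_edge.resize(ne);
  std::vector<int> fill(p.csr_off.begin(), p.csr_off.end() - 1);
  for (int e = 0; e < ne; ++e) p.csr_edge[fill[p.pre[e]]++] = e;
  return p;
}

// piecewise-linear schedule evaluation
struct Sched {
  std::vector<double> t, ach, ha, gaba;
  void at(double tt, double &a, double &h, double &g) const {
    int n = (int)t.size();
    if (tt <= t[0]) { a = ach[0]; h = ha[0]; g = gaba[0]; return; }
    if (tt >= t[n - 1]) { a = ach[n-1]; h = ha[n-1]; g = gaba[n-1]; return; }
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) { int mid = (lo + hi) / 2; (t[mid] <= tt ? lo : hi) = mid; }
    double f = (tt - t[lo]) / (t[lo + 1] - t[lo]);
    a = ach[lo] + f * (ach[lo + 1] - ach[lo]);
    h = ha[lo] + f * (ha[lo + 1] - ha[lo]);
    g = gaba[lo] + f * (gaba[lo + 1] - gaba[lo]);
  }
};

struct Stim { int pop, comp, lo, hi; double amp, t_on, t_off; };

} // namespace

double mini_next_time_cpp(double seed, double stream, double counter,
                          double t_ref, double rate_max, double tau_rise);

// Build the initial engine state: voltages at v_init, gates at steady state,
// calcium at rest, synapses closed with full depression resource.
// [[Rcpp::export]]
List engine_init(List params) {
  List pops = params["pops"];
  PopPar pp[4];
  for (int k = 0; k < 4; ++k) pp[k] = read_pop(pops[k]);
  double seed = getd(params, "seed");

  List st;
  st["version"] = 1.0;
  st["t"] = 0.0;
  const char *nm[4] = {"py", "inh", "tc", "re"};
  for (int k = 0; k < 4; ++k) {
    const PopPar &p = pp[k];
    int ncol = (k <= 1) ? CX_NCOL : (k == 2 ? TC_NCOL : RE_NCOL);
    NumericMatrix m(p.n, ncol);
    for (int i = 0; i < p.n; ++i) {
      double v = p.vinit;
      Rates r = traub_rates(v, p.vtraub);
      if (k <= 1) {
        m(i, cVS) = v; m(i, cVD) = v;
        m(i, cMS) = r.am / (r.am + r.bm);
        m(i, cHS) = r.ah / (r.ah + r.bh);
        m(i, cNS) = r.an / (r.an + r.bn);
        m(i, cMD) = m(i, cMS); m(i, cHD) = m(i, cHS);
        double a, b; km_rates(v, p.q, a, b);
        m(i, cMKM) = a / (a + b);
        kca_rates(p.ca_rest, p.kf_kca, p.b_kca, a, b);
        m(i, cMKCA) = a / (a + b);
        double am, bm, ah, bh; hva_rates(v, p.q, am, bm, ah, bh);
        m(i, cMHVA) = am / (am + bm); m(i, cHHVA) = ah / (ah + bh);
        m(i, cCA) = p.ca_rest; m(i, cLS) = -1e9;
      } else if (k == 2) {
        m(i, tV) = v;
        m(i, tM) = r.am / (r.am + r.bm);
        m(i, tH) = r.ah / (r.ah + r.bh);
        m(i, tN) = r.an / (r.an + r.bn);
        double minf, mtau, hinf, htau;
        it_tc(v, p.phi_m, p.phi_h, minf, mtau, hinf, htau);
        m(i, tMT) = minf; m(i, tHT) = hinf;
        double hs, ts; ih_voltage_gate(v, hs, ts);
        double ca4 = std::pow(p.ca_rest, 4.0);
        double p1 = p.k1 * ca4 / (p.k1 * ca4 + p.k2);
        m(i, tO) = hs; m(i, tOL) = 0.0; m(i, tP1) = p1;
        m(i, tCA) = p.ca_rest; m(i, tLS) = -1e9;
      } else {
        m(i, rV) = v;
        m(i, rM) = r.am / (r.am + r.bm);
        m(i, rH) = r.ah / (r.ah + r.bh);
        m(i, rN) = r.an / (r.an + r.bn);
        double minf, mtau, hinf, htau;
        it_re(v, p.phi_m, p.phi_h, minf, mtau, hinf, htau);
        m(i, rMT) = minf; m(i, rHT) = hinf;
        m(i, rCA) = p.ca_rest; m(i, rLS) = -1e9;
      }
    }
    st[nm[k]] = m;
  }

  List projs = params["projections"];
  List synst(projs.size());
  for (int q = 0; q < projs.size(); ++q) {
    List pl = projs[q];
    IntegerVector pre = pl["pre"];
    int ne = pre.size();
    double stream0 = getd(pl, "stream0");
    double rate = getd(pl, "mini_rate"), mtau = getd(pl, "mini_tau");
    bool minis = getd(pl, "minis") != 0;
    NumericVector O(ne), On(ne), Om(ne), E(ne, 1.0), tpre(ne, -1e9),
        tfire(ne, -1e9), tnext(ne), ctr(ne), Rg(ne), Gg(ne);
    for (int e = 0; e < ne; ++e) {
      if (minis && rate > 0) {
        tnext[e] = mini_next_time_cpp(seed, stream0 + e, 0.0, 0.0, rate, mtau);
        ctr[e] = 1.0;
      } else {
        tnext[e] = R_PosInf; ctr[e] = 0.0;
      }
    }
    synst[q] = List::create(_["O"] = O, _["On"] = On, _["Om"] = Om,
                            _["E"] = E, _["tpre"] = tpre, _["tfire"] = tfire,
                            _["tnext"] = tnext, _["ctr"] = ctr,
                            _["R"] = Rg, _["G"] = Gg);
  }
  st["syn"] = synst;
  return st;
}

double mini_next_time_cpp(double seed, double stream, double counter,
                          double t_ref, double rate_max, double tau_rise) {
  if (rate_max <= 0) return R_PosInf;
  double u = u01((std::uint64_t)seed, (std::uint64_t)stream,
                 (std::uint64_t)counter);
  return t_ref + mini_interval(u, rate_max, tau_rise);
}

// Advance the network by `duration` ms from `state`, recording samples every
// record_dt ms. Returns the final state plus raster, LFP and trace buffers.
// [[Rcpp::export]]
List engine_run(List params, List state, double duration) {
  const double dt = getd(params, "dt");
  if (dt <= 0) stop("dt must be positive");
  const double seed = getd(params, "seed");
  const double record_dt = getd(params, "record_dt");
  const double vthresh = getd(params, "spike_threshold");
  const double refrac = getd(params, "refractory");
  const double lambda_ampa = getd(params, "lambda_ampa");

  List pops = params["pops"];
  PopPar pp[4];
  for (int k = 0; k < 4; ++k) pp[k] = read_pop(pops[k]);

  List projl = params["projections"];
  std::vector<Proj> projs;
  for (int q = 0; q < projl.size(); ++q)
    projs.push_back(read_proj(projl[q], pp[(int)getd(as<List>(projl[q]), "sp")].n));
  for (auto &pr : projs) {
    double r_on = pr.alpha * pr.tmax + pr.beta;
    pr.don = std::exp(-dt * r_on);
    pr.oinf_on = pr.alpha * pr.tmax / r_on;
    pr.doff = std::exp(-dt * pr.beta);
    double rn_on = pr.alpha_n * pr.tmax + pr.beta_n;
    pr.don_n = std::exp(-dt * rn_on);
    pr.oinf_on_n = rn_on > 0 ? pr.alpha_n * pr.tmax / rn_on : 0;
    pr.doff_n = std::exp(-dt * pr.beta_n);
    double rr_on = pr.K1 * pr.tmax + pr.K2;
    pr.dron = std::exp(-dt * rr_on);
    pr.rinf_on = rr_on > 0 ? pr.K1 * pr.tmax / rr_on : 0;
    pr.droff = std::exp(-dt * pr.K2);
    pr.dgoff = std::exp(-dt * pr.K4);
  }

  Sched sched;
  {
    List sl = params["schedule"];
    sched.t = as<std::vector<double> >(sl["t"]);
    sched.ach = as<std::vector<double> >(sl["ach"]);
    sched.ha = as<std::vector<double> >(sl["ha"]);
    sched.gaba = as<std::vector<double> >(sl["gaba"]);
  }

  std::vector<Stim> stims;
  {
    List sl = params["stimulus"];
    for (int i = 0; i < sl.size(); ++i) {
      List s = sl[i];
      Stim st;
      st.pop = (int)getd(s, "pop"); st.comp = (int)getd(s, "comp");
      st.lo = (int)getd(s, "lo"); st.hi = (int)getd(s, "hi");
      st.amp = getd(s, "amp"); st.t_on = getd(s, "t_on");
      st.t_off = getd(s, "t_off");
      stims.push_back(st);
    }
  }

  // LFP coefficients (R_dend - R_soma, MOhm) for cortical cells
  std::vector<double> coef_py, coef_inh;
  {
    List ll = params["lfp"];
    coef_py = as<std::vector<double> >(ll["coef_py"]);
    coef_inh = as<std::vector<double> >(ll["coef_inh"]);
  }

  // trace recording selections
  std::vector<int> rec_pop, rec_idx, rec_comp;
  {
    List rl = params["record"];
    rec_pop = as<std::vector<int> >(rl["pop"]);
    rec_idx = as<std::vector<int> >(rl["idx"]);
    rec_comp = as<std::vector<int> >(rl["comp"]);
  }

  // copy state (the input list is not modified)
  double t0 = as<double>(state["t"]);
  NumericMatrix S[4];
  const char *nm[4] = {"py", "inh", "tc", "re"};
  for (int k = 0; k < 4; ++k) S[k] = clone(as<NumericMatrix>(state[nm[k]]));
  List synst_in = state["syn"];
  if (synst_in.size() != (int)projs.size())
    stop("state/parameter mismatch: %d synapse blocks for %d projections",
         (int)synst_in.size(), (int)projs.size());
  std::vector<NumericVector> sO, sOn, sOm, sE, stpre, stfire, stnext, sctr,
      sR, sG;
  for (int q = 0; q < (int)projs.size(); ++q) {
    List sl = synst_in[q];
    sO.push_back(clone(as<NumericVector>(sl["O"])));
    sOn.push_back(clone(as<NumericVector>(sl["On"])));
    sOm.push_back(clone(as<NumericVector>(sl["Om"])));
    sE.push_back(clone(as<NumericVector>(sl["E"])));
    stpre.push_back(clone(as<NumericVector>(sl["tpre"])));
    stfire.push_back(clone(as<NumericVector>(sl["tfire"])));
    stnext.push_back(clone(as<NumericVector>(sl["tnext"])));
    sctr.push_back(clone(as<NumericVector>(sl["ctr"])));
    sR.push_back(clone(as<NumericVector>(sl["R"])));
    sG.push_back(clone(as<NumericVector>(sl["G"])));
  }

  long long n_steps = (long long)llround(duration / dt);
  int every = (int)llround(record_dt / dt);
  if (every < 1) every = 1;
  long long gstep0 = (long long)llround(t0 / dt);

  // synaptic conductance accumulators per pop/compartment (mS/cm2 units
  // after division by area; accumulate in uS then scale)
  std::vector<double> Gs[4], GEs[4], Gd[4], GEd[4];
  for (int k = 0; k < 4; ++k) {
    Gs[k].assign(pp[k].n, 0.0); GEs[k].assign(pp[k].n, 0.0);
    Gd[k].assign(pp[k].n, 0.0); GEd[k].assign(pp[k].n, 0.0);
  }

  std::vector<double> ras_t; std::vector<int> ras_gid;
  int gid_off[4];
  gid_off[0] = 0; gid_off[1] = pp[0].n; gid_off[2] = gid_off[1] + pp[1].n;
  gid_off[3] = gid_off[2] + pp[2].n;

  long long n_samp_max = n_steps / every + 2;
  std::vector<double> samp_t, vsum, lfpbio;
  samp_t.reserve(n_samp_max); vsum.reserve(n_samp_max);
  lfpbio.reserve(n_samp_max);
  int ntr = (int)rec_pop.size();
  std::vector<std::vector<double> > traces(ntr);
  std::vector<double> lv_ach, lv_ha, lv_gaba;

  std::vector<int> spiked[4];

  auto record_sample = [&](double t) {
    samp_t.push_back(t);
    double a, h, g; sched.at(t, a, h, g);
    lv_ach.push_back(a); lv_ha.push_back(h); lv_gaba.push_back(g);
    double vs = 0;
    if (pp[0].n > 0) {
      for (int i = 0; i < pp[0].n; ++i) vs += S[0](i, cVD);
      vs /= pp[0].n;
    }
    vsum.push_back(vs);
    double phi = 0; // uV: MOhm * nA = mV -> *1000
    for (int i = 0; i < pp[0].n; ++i)
      phi += coef_py[i] * pp[0].gc * (S[0](i, cVS) - S[0](i, cVD));
    for (int i = 0; i < pp[1].n; ++i)
      phi += coef_inh[i] * pp[1].gc * (S[1](i, cVS) - S[1](i, cVD));
    lfpbio.push_back(phi * 1000.0);
    for (int j = 0; j < ntr; ++j) {
      const NumericMatrix &m = S[rec_pop[j]];
      int col = 0;
      if (rec_pop[j] <= 1) col = rec_comp[j] == 0 ? cVS : cVD;
      traces[j].push_back(m(rec_idx[j], col));
    }
  };

  if (n_steps == 0) record_sample(t0);

  for (long long step = 0; step < n_steps; ++step) {
    // time derived from the global step index so that a resumed run
    // reproduces the uninterrupted run bit for bit
    double t = (gstep0 + step) * dt;
    if ((gstep0 + step) % every == 0) record_sample(t);

    double ach, ha, gaba;
    sched.at(t, ach, ha, gaba);
    double ampa_scale = 1.0 + lambda_ampa * (1.0 - ach);
    double gkl_eff[4];
    for (int k = 0; k < 4; ++k)
      gkl_eff[k] = pp[k].gkl *
          (1.0 + pp[k].kappa_ach * (1.0 - ach) + pp[k].kappa_ha * (1.0 - ha));

    for (int k = 0; k < 4; ++k) {
      std::fill(Gs[k].begin(), Gs[k].end(), 0.0);
      std::fill(GEs[k].begin(), GEs[k].end(), 0.0);
      std::fill(Gd[k].begin(), Gd[k].end(), 0.0);
      std::fill(GEd[k].begin(), GEd[k].end(), 0.0);
    }

    // ---- synapse kinetics and conductance aggregation ----
    for (size_t q = 0; q < projs.size(); ++q) {
      Proj &pr = projs[q];
      int ne = (int)pr.pre.size();
      NumericVector &O = sO[q], &On = sOn[q], &Om = sOm[q], &E = sE[q],
                    &tpre = stpre[q], &tfire = stfire[q], &tnext = stnext[q],
                    &ctr = sctr[q], &Rg = sR[q], &Gg = sG[q];
      double wscale = 1.0;
      if (pr.mod_ampa) wscale = ampa_scale;
      if (pr.mod_gaba) wscale = gaba;
      NumericMatrix &T = S[pr.tp];
      int vcol = (pr.tp <= 1) ? (pr.comp == 0 ? cVS : cVD) : 0;
      std::vector<double> &Gacc = (pr.tp <= 1 && pr.comp == 1) ? Gd[pr.tp]
                                                               : Gs[pr.tp];
      std::vector<double> &GEacc = (pr.tp <= 1 && pr.comp == 1) ? GEd[pr.tp]
                                                                : GEs[pr.tp];
      for (int e = 0; e < ne; ++e) {
        // miniature events due now
        if (pr.minis && tnext[e] <= t) {
          tfire[e] = tnext[e];
          double tref = tnext[e];
          tnext[e] = mini_next_time_cpp(seed, pr.stream0 + e, ctr[e], tref,
                                        pr.mini_rate, pr.mini_tau);
          ctr[e] += 1.0;
        }
        double s = t - tpre[e];
        bool on = (s >= 0.0 && s < pr.tdur);
        if (pr.recep == 2) { // GABA-B
          if (on) Rg[e] = pr.rinf_on + (Rg[e] - pr.rinf_on) * pr.dron;
          else Rg[e] *= pr.droff;
          double ginf = pr.K3 * Rg[e] / pr.K4;
          Gg[e] = ginf + (Gg[e] - ginf) * pr.dgoff;
          double g4 = Gg[e] * Gg[e] * Gg[e] * Gg[e];
          double g = pr.w[e] * wscale * g4 / (g4 + pr.Kd); // uS
          Gacc[pr.post[e]] += g;
          GEacc[pr.post[e]] += g * pr.erev;
        } else {
          if (on) O[e] = pr.oinf_on + (O[e] - pr.oinf_on) * pr.don;
          else O[e] *= pr.doff;
          double g = pr.w[e] * wscale * (pr.dep ? E[e] : 1.0) * O[e];
          if (pr.minis) {
            double sm = t - tfire[e];
            bool mon = (sm >= 0.0 && sm < pr.tdur);
            if (mon) Om[e] = pr.oinf_on + (Om[e] - pr.oinf_on) * pr.don;
            else Om[e] *= pr.doff;
            g += pr.w[e] * wscale * pr.mini_amp * Om[e];
          }
          if (pr.wn[e] > 0) { // NMDA share
            if (on) On[e] = pr.oinf_on_n + (On[e] - pr.oinf_on_n) * pr.don_n;
            else On[e] *= pr.doff_n;
            double b = somnotc::nmda_mg_block(T(pr.post[e], vcol), 1.0);
            g += pr.wn[e] * wscale * On[e] * b;
          }
          Gacc[pr.post[e]] += g;
          GEacc[pr.post[e]] += g * pr.erev;
        }
      }
    }

    // ---- stimulus currents (uA/cm2, applied to B accumulators later) ----
    // handled inline per cell below via lambda
    auto stim_for = [&](int pop, int comp, int i) {
      double amp = 0;
      for (auto &st : stims) {
        if (st.pop != pop || st.comp != comp) continue;
        if (t < st.t_on || t >= st.t_off) continue;
        if (st.lo >= 0 && (i < st.lo || i > st.hi)) continue;
        amp += st.amp;
      }
      return amp;
    };

    // ---- cell updates ----
    for (int k = 0; k < 4; ++k) spiked[k].clear();

    for (int k = 0; k < 2; ++k) { // PY, INH
      const PopPar &p = pp[k];
      double gcs = p.gc * 1e-3 / p.area_s; // mS/cm2
      double gcd = p.gc * 1e-3 / p.area_d;
      for (int i = 0; i < p.n; ++i) {
        double vs = S[k](i, cVS), vd = S[k](i, cVD);
        // soma gates
        Rates rs = traub_rates(vs, p.vtraub);
        double ms = exp_gate(S[k](i, cMS), rs.am / (rs.am + rs.bm),
                             1.0 / (rs.am + rs.bm), dt);
        double hs = exp_gate(S[k](i, cHS), rs.ah / (rs.ah + rs.bh),
                             1.0 / (rs.ah + rs.bh), dt);
        double ns = exp_gate(S[k](i, cNS), rs.an / (rs.an + rs.bn),
                             1.0 / (rs.an + rs.bn), dt);
        // dendrite gates
        Rates rd = traub_rates(vd, p.vtraub);
        double md = exp_gate(S[k](i, cMD), rd.am / (rd.am + rd.bm),
                             1.0 / (rd.am + rd.bm), dt);
        double hd = exp_gate(S[k](i, cHD), rd.ah / (rd.ah + rd.bh),
                             1.0 / (rd.ah + rd.bh), dt);
        double a, b;
        km_rates(vd, p.q, a, b);
        double mkm = exp_gate(S[k](i, cMKM), a / (a + b), 1.0 / (a + b), dt);
        double ca = S[k](i, cCA);
        kca_rates(ca, p.kf_kca, p.b_kca, a, b);
        double mkca = exp_gate(S[k](i, cMKCA), a / (a + b), 1.0 / (a + b), dt);
        double am, bm, ah, bh;
        hva_rates(vd, p.q, am, bm, ah, bh);
        double mhva = exp_gate(S[k](i, cMHVA), am / (am + bm),
                               1.0 / (am + bm), dt);
        double hhva = exp_gate(S[k](i, cHHVA), ah / (ah + bh),
                               1.0 / (ah + bh), dt);
        double eca = somnotc::nernst_eca(ca, p.ca_out, p.temp);
        // conductances (mS/cm2)
        double gna_s = p.gna_s * ms * ms * ms * hs;
        double gk_s = p.gk_s * ns * ns * ns * ns;
        double gnap_s = p.gnap_s * nap_minf(vs);
        double gna_d = p.gna_d * md * md * md * hd;
        double gnap_d = p.gnap_d * nap_minf(vd);
        double gkm_d = p.gkm * mkm;
        double gkca_d = p.gkca * mkca;
        double ghva_d = p.ghva * mhva * mhva * hhva;
        // calcium update from HVA current at old voltage
        double ihva = ghva_d * (vd - eca);
        S[k](i, cCA) = [&]{
          double cinf = p.ca_rest - p.ca_k * p.ca_tau * ihva;
          double out = cinf + (ca - cinf) * std::exp(-dt / p.ca_tau);
          return out > 1e-8 ? out : 1e-8;
        }();
        // synaptic (uS -> mS/cm2 on the target compartment)
        double gsyn_s = Gs[k][i] * 1e-3 / p.area_s;
        double gesyn_s = GEs[k][i] * 1e-3 / p.area_s;
        double gsyn_d = Gd[k][i] * 1e-3 / p.area_d;
        double gesyn_d = GEd[k][i] * 1e-3 / p.area_d;
        // semi-implicit 2x2 solve
        double Gtot_s = gna_s + gk_s + gnap_s + gsyn_s;
        double Bs = gna_s * p.ena + gk_s * p.ek + gnap_s * p.ena + gesyn_s +
                    stim_for(k, 0, i);
        double Gtot_d = gna_d + gnap_d + gkm_d + gkca_d + ghva_d +
                        gkl_eff[k] + p.gl + gsyn_d;
        double Bd = (gna_d + gnap_d) * p.ena + (gkm_d + gkca_d) * p.ek +
                    ghva_d * eca + gkl_eff[k] * p.ek + p.gl * p.el +
                    gesyn_d + stim_for(k, 1, i);
        double cdt = p.cm / dt;
        double a11 = cdt + Gtot_s + gcs, a12 = -gcs;
        double a21 = -gcd, a22 = cdt + Gtot_d + gcd;
        double b1 = cdt * vs + Bs, b2 = cdt * vd + Bd;
        double det = a11 * a22 - a12 * a21;
        double vs_n = (b1 * a22 - a12 * b2) / det;
        double vd_n = (a11 * b2 - b1 * a21) / det;
        if (!std::isfinite(vs_n) || !std::isfinite(vd_n))
          stop("voltage diverged: population %d cell %d at t=%.3f ms", k, i, t);
        S[k](i, cMS) = ms; S[k](i, cHS) = hs; S[k](i, cNS) = ns;
        S[k](i, cMD) = md; S[k](i, cHD) = hd; S[k](i, cMKM) = mkm;
        S[k](i, cMKCA) = mkca; S[k](i, cMHVA) = mhva; S[k](i, cHHVA) = hhva;
        S[k](i, cVS) = vs_n; S[k](i, cVD) = vd_n;
        if (vs < vthresh && vs_n >= vthresh &&
            (t + dt) - S[k](i, cLS) > refrac) {
          spiked[k].push_back(i);
          S[k](i, cLS) = t + dt;
          ras_gid.push_back(gid_off[k] + i);
          ras_t.push_back(t + dt);
        }
      }
    }

    { // TC
      const PopPar &p = pp[2];
      for (int i = 0; i < p.n; ++i) {
        double v = S[2](i, tV);
        Rates r = traub_rates(v, p.vtraub);
        double m = exp_gate(S[2](i, tM), r.am / (r.am + r.bm),
                            1.0 / (r.am + r.bm), dt);
        double h = exp_gate(S[2](i, tH), r.ah / (r.ah + r.bh),
                            1.0 / (r.ah + r.bh), dt);
        double n = exp_gate(S[2](i, tN), r.an / (r.an + r.bn),
                            1.0 / (r.an + r.bn), dt);
        double minf, mtau, hinf, htau;
        it_tc(v, p.phi_m, p.phi_h, minf, mtau, hinf, htau);
        double mt = exp_gate(S[2](i, tMT), minf, mtau, dt);
        double ht = exp_gate(S[2](i, tHT), hinf, htau, dt);
        double ca = S[2](i, tCA);
        double O = S[2](i, tO), OL = S[2](i, tOL), P1 = S[2](i, tP1);
        IhPar ip; ip.k1 = p.k1; ip.k2 = p.k2; ip.k3 = p.k3; ip.k4 = p.k4;
        ip.ginc = p.ginc; ip.eh = p.eh;
        ih_step(v, ca, dt, ip, O, OL, P1);
        double eca = somnotc::nernst_eca(ca, p.ca_out, p.temp);
        double git = p.gt * mt * mt * ht;
        double ica = git * (v - eca);
        {
          double cinf = p.ca_rest - p.ca_k * p.ca_tau * ica;
          double out = cinf + (ca - cinf) * std::exp(-dt / p.ca_tau);
          S[2](i, tCA) = out > 1e-8 ? out : 1e-8;
        }
        double gna = p.gna * m * m * m * h;
        double gk = p.gk * n * n * n * n;
        double gh = p.gh * (O + p.ginc * OL);
        double gsyn = Gs[2][i] * 1e-3 / p.area_s;
        double gesyn = GEs[2][i] * 1e-3 / p.area_s;
        double Gtot = gna + gk + git + gh + gkl_eff[2] + p.gl + gsyn;
        double B = gna * p.ena + gk * p.ek + git * eca + gh * p.eh +
                   gkl_eff[2] * p.ek + p.gl * p.el + gesyn +
                   stim_for(2, 0, i);
        double cdt = p.cm / dt;
        double vn = (cdt * v + B) / (cdt + Gtot);
        if (!std::isfinite(vn))
          stop("voltage diverged: population 2 cell %d at t=%.3f ms", i, t);
        S[2](i, tM) = m; S[2](i, tH) = h; S[2](i, tN) = n;
        S[2](i, tMT) = mt; S[2](i, tHT) = ht;
        S[2](i, tO) = O; S[2](i, tOL) = OL; S[2](i, tP1) = P1;
        S[2](i, tV) = vn;
        if (v < vthresh && vn >= vthresh && (t + dt) - S[2](i, tLS) > refrac) {
          spiked[2].push_back(i);
          S[2](i, tLS) = t + dt;
          ras_gid.push_back(gid_off[2] + i);
          ras_t.push_back(t + dt);
        }
      }
    }

    { // RE
      const PopPar &p = pp[3];
      for (int i = 0; i < p.n; ++i) {
        double v = S[3](i, rV);
        Rates r = traub_rates(v, p.vtraub);
        double m = exp_gate(S[3](i, rM), r.am / (r.am + r.bm),
                            1.0 / (r.am + r.bm), dt);
        double h = exp_gate(S[3](i, rH), r.ah / (r.ah + r.bh),
                            1.0 / (r.ah + r.bh), dt);
        double n = exp_gate(S[3](i, rN), r.an / (r.an + r.bn),
                            1.0 / (r.an + r.bn), dt);
        double minf, mtau, hinf, htau;
        it_re(v, p.phi_m, p.phi_h, minf, mtau, hinf, htau);
        double mt = exp_gate(S[3](i, rMT), minf, mtau, dt);
        double ht = exp_gate(S[3](i, rHT), hinf, htau, dt);
        double ca = S[3](i, rCA);
        double eca = somnotc::nernst_eca(ca, p.ca_out, p.temp);
        double git = p.gt * mt * mt * ht;
        double ica = git * (v - eca);
        {
          double cinf = p.ca_rest - p.ca_k * p.ca_tau * ica;
          double out = cinf + (ca - cinf) * std::exp(-dt / p.ca_tau);
          S[3](i, rCA) = out > 1e-8 ? out : 1e-8;
        }
        double gna = p.gna * m * m * m * h;
        double gk = p.gk * n * n * n * n;
        double gsyn = Gs[3][i] * 1e-3 / p.area_s;
        double gesyn = GEs[3][i] * 1e-3 / p.area_s;
        double Gtot = gna + gk + git + gkl_eff[3] + p.gl + gsyn;
        double B = gna * p.ena + gk * p.ek + git * eca + gkl_eff[3] * p.ek +
                   p.gl * p.el + gesyn + stim_for(3, 0, i);
        double cdt = p.cm / dt;
        double vn = (cdt * v + B) / (cdt + Gtot);
        if (!std::isfinite(vn))
          stop("voltage diverged: population 3 cell %d at t=%.3f ms", i, t);
        S[3](i, rM) = m; S[3](i, rH) = h; S[3](i, rN) = n;
        S[3](i, rMT) = mt; S[3](i, rHT) = ht; S[3](i, rV) = vn;
        if (v < vthresh && vn >= vthresh && (t + dt) - S[3](i, rLS) > refrac) {
          spiked[3].push_back(i);
          S[3](i, rLS) = t + dt;
          ras_gid.push_back(gid_off[3] + i);
          ras_t.push_back(t + dt);
        }
      }
    }

    // ---- presynaptic events: depression, transmitter pulses, mini reset ----
    for (size_t q = 0; q < projs.size(); ++q) {
      Proj &pr = projs[q];
      if (spiked[pr.sp].empty()) continue;
      NumericVector &E = sE[q], &tpre = stpre[q], &tnext = stnext[q],
                    &ctr = sctr[q];
      double tsp = t + dt;
      for (int i : spiked[pr.sp]) {
        for (int idx = pr.csr_off[i]; idx < pr.csr_off[i + 1]; ++idx) {
          int e = pr.csr_edge[idx];
          if (pr.dep) {
            double prev = tpre[e] - pr.delay;
            double isi = tsp - prev;
            E[e] = somnotc::depression_update(E[e], isi, pr.U, pr.tau_d);
          }
          tpre[e] = tsp + pr.delay;
          if (pr.minis && pr.mini_rate > 0) {
            tnext[e] = mini_next_time_cpp(seed, pr.stream0 + e, ctr[e], tsp,
                                          pr.mini_rate, pr.mini_tau);
            ctr[e] += 1.0;
          }
        }
      }
    }
  }

  double t_end = (gstep0 + n_steps) * dt;

  List synst(projs.size());
  for (int q = 0; q < (int)projs.size(); ++q)
    synst[q] = List::create(_["O"] = sO[q], _["On"] = sOn[q], _["Om"] = sOm[q],
                            _["E"] = sE[q], _["tpre"] = stpre[q],
                            _["tfire"] = stfire[q], _["tnext"] = stnext[q],
                            _["ctr"] = sctr[q], _["R"] = sR[q],
                            _["G"] = sG[q]);
  List st_out = List::create(
      _["version"] = 1.0, _["t"] = t_end, _["py"] = S[0], _["inh"] = S[1],
      _["tc"] = S[2], _["re"] = S[3], _["syn"] = synst);

  NumericMatrix trm((int)samp_t.size(), ntr);
  for (int j = 0; j < ntr; ++j)
    for (size_t s = 0; s < samp_t.size(); ++s) trm(s, j) = traces[j][s];
  NumericMatrix lvm((int)samp_t.size(), 3);
  for (size_t s = 0; s < samp_t.size(); ++s) {
    lvm(s, 0) = lv_ach[s]; lvm(s, 1) = lv_ha[s]; lvm(s, 2) = lv_gaba[s];
  }

  return List::create(
      _["state"] = st_out,
      _["spike_gid"] = wrap(ras_gid), _["spike_t"] = wrap(ras_t),
      _["sample_t"] = wrap(samp_t), _["lfp_vsum"] = wrap(vsum),
      _["lfp_bio"] = wrap(lfpbio), _["traces"] = trm, _["levels"] = lvm);
}
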