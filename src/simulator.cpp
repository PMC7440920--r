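// Fixed-step conductance-based network integrator.
//
// Cortical PY/IN neurons: two compartments; the dendrite carries
// I_Na, I_NaP, I_Km, I_KCa, I_HVA, the ACh-scaled K leak and a Cl leak;
// the axo-somatic compartment (I_Na, I_NaP, I_K) is treated as fast and
// solved algebraically from its current balance each step.  Thalamic
// TC/RE neurons: single compartment with I_Na, I_K, K leak, I_T, Cl
// leak, and (TC only) I_h whose activation curve is shifted by the
// histamine level.  Gating variables use the exact exponential update
// with voltage-indexed lookup tables; the temperature factor
// QT = Q^((T-23)/10) scales the cortical gating rates (fast thalamic
// spike currents and the I_T / I_h time constants are specified at
// body temperature already).
//
// Synapses: per-projection aggregated open fractions with exponential
// decay (AMPA/NMDA/GABA_A) or a two-stage rise/decay cascade (GABA_B),
// per-presynaptic-neuron short-term depression of intracortical AMPA,
// miniature PSPs as inhomogeneous Poisson processes sampled by
// thinning, and nearest-neighbour STDP on the plastic PY->PY layer.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <random>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// parameters

struct Params {
  // cortical two-compartment (absolute conductances, uS; C in nF)
  double py_cm_d, py_g_couple;
  double py_gna_d, py_gnap_d, py_gkm, py_gkca, py_ghva, py_gkl, py_gl;
  double py_gna_s, py_gk_s, py_gnap_s;
  double in_cm_d, in_g_couple;
  double in_gna_d, in_gkm, in_gkca, in_ghva, in_gkl, in_gl;
  double in_gna_s, in_gk_s;
  double e_na, e_k, e_ca, e_cl, e_h;
  double ca_tau, ca_inf, ca_gain;
  // thalamic single-compartment (density units, mS/cm2; C = 1 uF/cm2)
  double tc_cm, tc_gna, tc_gk, tc_gt, tc_gh, tc_gkl, tc_gl, tc_el, tc_vt;
  double re_cm, re_gna, re_gk, re_gt, re_gkl, re_gl, re_el, re_vt;
  // synapses
  double tau_ampa, tau_nmda, tau_gabaa, gabab_tau_r, gabab_tau_d;
  double e_ampa, e_gabaa, e_gabab;
  double mg_vhalf, mg_k;
  double qt;
  // minis
  double mini_py_py, mini_py_in, mini_in_py, mini_upsilon, mini_max_rate;
  // short-term depression
  double dep_U, dep_tau;
  double spike_thresh, refrac;
};

static double getd(const List& L, const char* nm) {
  if (!L.containsElementNamed(nm))
    stop("simulation parameter '%s' missing", nm);
  return as<double>(L[nm]);
}

static Params read_params(const List& L) {
  Params p;
  p.py_cm_d = getd(L, "py_cm_d"); p.py_g_couple = getd(L, "py_g_couple");
  p.py_gna_d = getd(L, "py_gna_d"); p.py_gnap_d = getd(L, "py_gnap_d");
  p.py_gkm = getd(L, "py_gkm"); p.py_gkca = getd(L, "py_gkca");
  p.py_ghva = getd(L, "py_ghva"); p.py_gkl = getd(L, "py_gkl");
  p.py_gl = getd(L, "py_gl");
  p.py_gna_s = getd(L, "py_gna_s"); p.py_gk_s = getd(L, "py_gk_s");
  p.py_gnap_s = getd(L, "py_gnap_s");
  p.in_cm_d = getd(L, "in_cm_d"); p.in_g_couple = getd(L, "in_g_couple");
  p.in_gna_d = getd(L, "in_gna_d"); p.in_gkm = getd(L, "in_gkm");
  p.in_gkca = getd(L, "in_gkca"); p.in_ghva = getd(L, "in_ghva");
  p.in_gkl = getd(L, "in_gkl"); p.in_gl = getd(L, "in_gl");
  p.in_gna_s = getd(L, "in_gna_s"); p.in_gk_s = getd(L, "in_gk_s");
  p.e_na = getd(L, "e_na"); p.e_k = getd(L, "e_k"); p.e_ca = getd(L, "e_ca");
  p.e_cl = getd(L, "e_cl"); p.e_h = getd(L, "e_h");
  p.ca_tau = getd(L, "ca_tau"); p.ca_inf = getd(L, "ca_inf");
  p.ca_gain = getd(L, "ca_gain");
  p.tc_cm = getd(L, "tc_cm"); p.tc_gna = getd(L, "tc_gna");
  p.tc_gk = getd(L, "tc_gk"); p.tc_gt = getd(L, "tc_gt");
  p.tc_gh = getd(L, "tc_gh"); p.tc_gkl = getd(L, "tc_gkl");
  p.tc_gl = getd(L, "tc_gl"); p.tc_el = getd(L, "tc_el");
  p.tc_vt = getd(L, "tc_vt");
  p.re_cm = getd(L, "re_cm"); p.re_gna = getd(L, "re_gna");
  p.re_gk = getd(L, "re_gk"); p.re_gt = getd(L, "re_gt");
  p.re_gkl = getd(L, "re_gkl"); p.re_gl = getd(L, "re_gl");
  p.re_el = getd(L, "re_el"); p.re_vt = getd(L, "re_vt");
  p.tau_ampa = getd(L, "tau_ampa"); p.tau_nmda = getd(L, "tau_nmda");
  p.tau_gabaa = getd(L, "tau_gabaa");
  p.gabab_tau_r = getd(L, "gabab_tau_r"); p.gabab_tau_d = getd(L, "gabab_tau_d");
  p.e_ampa = getd(L, "e_ampa"); p.e_gabaa = getd(L, "e_gabaa");
  p.e_gabab = getd(L, "e_gabab");
  p.mg_vhalf = getd(L, "mg_vhalf"); p.mg_k = getd(L, "mg_k");
  p.qt = getd(L, "qt");
  p.mini_py_py = getd(L, "mini_py_py"); p.mini_py_in = getd(L, "mini_py_in");
  p.mini_in_py = getd(L, "mini_in_py");
  p.mini_upsilon = getd(L, "mini_upsilon");
  p.mini_max_rate = getd(L, "mini_max_rate");
  p.dep_U = getd(L, "dep_U"); p.dep_tau = getd(L, "dep_tau");
  p.spike_thresh = getd(L, "spike_thresh"); p.refrac = getd(L, "refrac");
  return p;
}

// arousal scalars (order fixed; see state_scalars() on the R side)
struct Modulation {
  double gamma_in, gamma_re, ach_ampa_py, ach_ampa_tc;
  double achgkl_py, achgkl_in, achgkl_tc, achgkl_re;
  double ha_gh;
};

static Modulation read_mod(const NumericVector& v) {
  if (v.size() != 9) stop("arousal scalar vector must have 9 elements");
  Modulation m;
  m.gamma_in = v[0]; m.gamma_re = v[1];
  m.ach_ampa_py = v[2]; m.ach_ampa_tc = v[3];
  m.achgkl_py = v[4]; m.achgkl_in = v[5];
  m.achgkl_tc = v[6]; m.achgkl_re = v[7];
  m.ha_gh = v[8];
  return m;
}

// ---------------------------------------------------------------------------
// gating rate functions

static inline double vtrap(double x, double y) {
  // x / (1 - exp(-x/y)) without the removable singularity at x = 0
  return (std::fabs(x / y) < 1e-6) ? y * (1.0 + x / (2.0 * y)) : x / (1.0 - std::exp(-x / y));
}

// cortical fast Na (dendritic and axo-somatic)
static inline double cna_am(double v) { return 0.182 * vtrap(v + 25.0, 9.0); }
static inline double cna_bm(double v) { return 0.124 * vtrap(-(v + 25.0), 9.0); }
static inline double cna_ah(double v) { return 0.024 * vtrap(v + 45.0, 5.0); }
static inline double cna_bh(double v) { return 0.0091 * vtrap(-(v + 70.0), 5.0); }
static inline double cna_hinf(double v) { return 1.0 / (1.0 + std::exp((v + 60.0) / 6.2)); }
// axo-somatic fast K (delayed rectifier, Traub kinetics shifted to a
// cortical threshold; rates specified at body temperature)
static inline double ck_an(double v) { return 0.032 * vtrap(v + 40.0, 5.0); }
static inline double ck_bn(double v) { return 0.5 * std::exp(-(v + 45.0) / 40.0); }
// slow non-inactivating K (Km)
static inline double km_an(double v) { return 0.001 * vtrap(v + 30.0, 9.0); }
static inline double km_bn(double v) { return 0.001 * vtrap(-(v + 30.0), 9.0); }
// high-threshold Ca
static inline double hva_am(double v) { return 0.055 * vtrap(v + 27.0, 3.8); }
static inline double hva_bm(double v) { return 0.94 * std::exp(-(v + 75.0) / 17.0); }
static inline double hva_ah(double v) { return 0.000457 * std::exp(-(v + 13.0) / 50.0); }
static inline double hva_bh(double v) { return 0.0065 / (1.0 + std::exp(-(v + 15.0) / 28.0)); }
// persistent Na: fast sigmoid activation
static inline double nap_minf(double v) { return 1.0 / (1.0 + std::exp(-(v + 42.0) / 5.0)); }

// thalamic fast spike currents (Traub kinetics, threshold-shifted)
static inline double tna_am(double v, double vt) { return 0.32 * vtrap((v - vt) - 13.0, 4.0); }
static inline double tna_bm(double v, double vt) { return 0.28 * vtrap(40.0 - (v - vt), 5.0); }
static inline double tna_ah(double v, double vt) { return 0.128 * std::exp((17.0 - (v - vt)) / 18.0); }
static inline double tna_bh(double v, double vt) { return 4.0 / (1.0 + std::exp((40.0 - (v - vt)) / 5.0)); }
static inline double tk_an(double v, double vt) { return 0.032 * vtrap((v - vt) - 15.0, 5.0); }
static inline double tk_bn(double v, double vt) { return 0.5 * std::exp((10.0 - (v - vt)) / 40.0); }

// low-threshold Ca, TC variant (time constants at body temperature)
static inline double tct_minf(double v) { return 1.0 / (1.0 + std::exp(-(v + 57.0) / 6.2)); }
static inline double tct_taum(double v) {
  return (0.612 + 1.0 / (std::exp(-(v + 132.0) / 16.7) + std::exp((v + 16.8) / 18.2))) / 3.74;
}
static inline double tct_hinf(double v) { return 1.0 / (1.0 + std::exp((v + 81.0) / 4.0)); }
static inline double tct_tauh(double v) {
  double t = (v < -80.0) ? std::exp((v + 467.0) / 66.6)
                         : 28.0 + std::exp(-(v + 22.0) / 10.5);
  return t / 3.74;
}
// low-threshold Ca, RE variant
static inline double ret_minf(double v) { return 1.0 / (1.0 + std::exp(-(v + 52.0) / 7.4)); }
static inline double ret_taum(double v) {
  return (3.0 + 1.0 / (std::exp((v + 27.0) / 10.0) + std::exp(-(v + 102.0) / 15.0))) / 3.0;
}
static inline double ret_hinf(double v) { return 1.0 / (1.0 + std::exp((v + 80.0) / 5.0)); }
static inline double ret_tauh(double v) {
  return (85.0 + 1.0 / (std::exp((v + 48.0) / 4.0) + std::exp(-(v + 407.0) / 50.0))) / 3.0;
}
// hyperpolarization-activated mixed cation current (TC)
static inline double ih_minf(double v, double shift) {
  return 1.0 / (1.0 + std::exp((v + 75.0 + shift) / 5.5));
}
static inline double ih_tau(double v) {
  return 20.0 + 1000.0 / (std::exp((v + 71.5) / 14.2) + std::exp(-(v + 89.0) / 11.6));
}

// ---------------------------------------------------------------------------
// gating lookup tables: x_inf(V) and exp(-dt/tau(V)) on a voltage grid

struct Table {
  double vmin = -130.0, vmax = 60.0, dv = 0.05;
  std::vector<double> xinf, efac;
  template <class FA, class FB>
  void build_rates(FA alpha, FB beta, double qt, double dt) {
    int n = (int)((vmax - vmin) / dv) + 2;
    xinf.resize(n); efac.resize(n);
    for (int i = 0; i < n; ++i) {
      double v = vmin + i * dv;
      double a = alpha(v), b = beta(v);
      xinf[i] = a / (a + b);
      efac[i] = std::exp(-dt * (a + b) * qt);
    }
  }
  template <class FI, class FT>
  void build_tau(FI xinf_f, FT tau_f, double dt) {
    int n = (int)((vmax - vmin) / dv) + 2;
    xinf.resize(n); efac.resize(n);
    for (int i = 0; i < n; ++i) {
      double v = vmin + i * dv;
      xinf[i] = xinf_f(v);
      efac[i] = std::exp(-dt / tau_f(v));
    }
  }
  inline void step(double v, double& x) const {
    double u = (v - vmin) / dv;
    if (u < 0) u = 0;
    int i = (int)u;
    if (i >= (int)xinf.size() - 1) i = (int)xinf.size() - 2;
    double f = u - i;
    double xi = xinf[i] + f * (xinf[i + 1] - xinf[i]);
    double ef = efac[i] + f * (efac[i + 1] - efac[i]);
    x = xi + (x - xi) * ef;
  }
};

struct Tables {
  double dt = -1.0, ha_gh = 1e99;
  Table cna_m, cna_h, ck_n, km_n, hva_m, hva_h, sna_m, sna_h;
  Table tna_m_tc, tna_h_tc, tk_n_tc, tna_m_re, tna_h_re, tk_n_re;
  Table tct_m, tct_h, ret_m, ret_h, ih_m;
  void build(const Params& p, double dt_, double ha) {
    if (dt == dt_ && ha_gh == ha) return;
    dt = dt_; ha_gh = ha;
    cna_m.build_rates(cna_am, cna_bm, p.qt, dt);
    // Na inactivation: steady state from its own sigmoid, tau from rates
    {
      int n = (int)((cna_h.vmax - cna_h.vmin) / cna_h.dv) + 2;
      cna_h.xinf.resize(n); cna_h.efac.resize(n);
      for (int i = 0; i < n; ++i) {
        double v = cna_h.vmin + i * cna_h.dv;
        double a = cna_ah(v), b = cna_bh(v);
        cna_h.xinf[i] = cna_hinf(v);
        cna_h.efac[i] = std::exp(-dt * (a + b) * p.qt);
      }
    }
    ck_n.build_rates(ck_an, ck_bn, 1.0, dt);
    // axo-somatic fast Na: Traub kinetics at a cortical threshold
    {
      const double vtc = -55.0;
      sna_m.build_rates([vtc](double v){ return tna_am(v, vtc); },
                        [vtc](double v){ return tna_bm(v, vtc); }, 1.0, dt);
      sna_h.build_rates([vtc](double v){ return tna_ah(v, vtc); },
                        [vtc](double v){ return tna_bh(v, vtc); }, 1.0, dt);
    }
    km_n.build_rates(km_an, km_bn, p.qt, dt);
    hva_m.build_rates(hva_am, hva_bm, p.qt, dt);
    hva_h.build_rates(hva_ah, hva_bh, p.qt, dt);
    double vt_tc = p.tc_vt, vt_re = p.re_vt;
    tna_m_tc.build_rates([vt_tc](double v){ return tna_am(v, vt_tc); },
                         [vt_tc](double v){ return tna_bm(v, vt_tc); }, 1.0, dt);
    tna_h_tc.build_rates([vt_tc](double v){ return tna_ah(v, vt_tc); },
                         [vt_tc](double v){ return tna_bh(v, vt_tc); }, 1.0, dt);
    tk_n_tc.build_rates([vt_tc](double v){ return tk_an(v, vt_tc); },
                        [vt_tc](double v){ return tk_bn(v, vt_tc); }, 1.0, dt);
    tna_m_re.build_rates([vt_re](double v){ return tna_am(v, vt_re); },
                         [vt_re](double v){ return tna_bm(v, vt_re); }, 1.0, dt);
    tna_h_re.build_rates([vt_re](double v){ return tna_ah(v, vt_re); },
                         [vt_re](double v){ return tna_bh(v, vt_re); }, 1.0, dt);
    tk_n_re.build_rates([vt_re](double v){ return tk_an(v, vt_re); },
                        [vt_re](double v){ return tk_bn(v, vt_re); }, 1.0, dt);
    tct_m.build_tau(tct_minf, tct_taum, dt);
    tct_h.build_tau(tct_hinf, tct_tauh, dt);
    ret_m.build_tau(ret_minf, ret_taum, dt);
    ret_h.build_tau(ret_hinf, ret_tauh, dt);
    ih_m.build_tau([ha](double v){ return ih_minf(v, ha); }, ih_tau, dt);
  }
};

// ---------------------------------------------------------------------------
// neuron state

struct CortState {                 // PY / IN
  double vd, vs;
  double m_d, h_d, nap_m, km_n, kca_m, hva_m, hva_h, ca;
  double m_s, h_s, n_s, nap_s;
};

struct ThalState {                 // TC / RE
  double v;
  double m, h, n, t_m, t_h, ih_m;
};

static void init_cort(CortState& s, double v0) {
  s.vd = s.vs = v0;
  double a = cna_am(v0), b = cna_bm(v0);
  s.m_d = s.m_s = a / (a + b);
  s.h_d = s.h_s = cna_hinf(v0);
  s.nap_m = nap_minf(v0); s.nap_s = s.nap_m;
  a = km_an(v0); b = km_bn(v0); s.km_n = a / (a + b);
  s.kca_m = 0.0;
  a = hva_am(v0); b = hva_bm(v0); s.hva_m = a / (a + b);
  a = hva_ah(v0); b = hva_bh(v0); s.hva_h = a / (a + b);
  s.ca = 0.1;
  a = ck_an(v0); b = ck_bn(v0); s.n_s = a / (a + b);
}

static void init_thal(ThalState& s, double v0, double vt, bool is_tc, double ha) {
  s.v = v0;
  double a = tna_am(v0, vt), b = tna_bm(v0, vt);
  s.m = a / (a + b);
  a = tna_ah(v0, vt); b = tna_bh(v0, vt); s.h = a / (a + b);
  a = tk_an(v0, vt); b = tk_bn(v0, vt); s.n = a / (a + b);
  if (is_tc) { s.t_m = tct_minf(v0); s.t_h = tct_hinf(v0); s.ih_m = ih_minf(v0, ha); }
  else { s.t_m = ret_minf(v0); s.t_h = ret_hinf(v0); s.ih_m = 0.0; }
}

// one integration step of a cortical neuron.  isyn_d: total synaptic +
// stimulation current on the dendrite (nA, positive = outward).
// Returns the new somatic voltage.
static inline void step_cort(CortState& s, const Params& p, const Tables& tb,
                             bool is_py, double gkl_scale,
                             double isyn_d, double dt) {
  double cm = is_py ? p.py_cm_d : p.in_cm_d;
  double gc = is_py ? p.py_g_couple : p.in_g_couple;
  double gna_d = is_py ? p.py_gna_d : p.in_gna_d;
  double gkm = is_py ? p.py_gkm : p.in_gkm;
  double gkca = is_py ? p.py_gkca : p.in_gkca;
  double ghva = is_py ? p.py_ghva : p.in_ghva;
  double gkl = (is_py ? p.py_gkl : p.in_gkl) * gkl_scale;
  double gl = is_py ? p.py_gl : p.in_gl;

  // gating at dendritic voltage
  tb.cna_m.step(s.vd, s.m_d);
  tb.cna_h.step(s.vd, s.h_d);
  tb.km_n.step(s.vd, s.km_n);
  tb.hva_m.step(s.vd, s.hva_m);
  tb.hva_h.step(s.vd, s.hva_h);
  s.nap_m = nap_minf(s.vd);
  // KCa: alpha = 0.01 * [Ca], beta = 0.02 (Ca in uM)
  {
    double a = 0.01 * s.ca, b = 0.02;
    double xinf = a / (a + b);
    s.kca_m = xinf + (s.kca_m - xinf) * std::exp(-dt * (a + b) * p.qt);
  }
  double i_na  = gna_d * s.m_d * s.m_d * s.m_d * s.h_d * (s.vd - p.e_na);
  double i_nap = (is_py ? p.py_gnap_d : 0.0) * s.nap_m * (s.vd - p.e_na);
  double i_km  = gkm * s.km_n * (s.vd - p.e_k);
  double i_kca = gkca * s.kca_m * (s.vd - p.e_k);
  double i_hva = ghva * s.hva_m * s.hva_m * s.hva_h * (s.vd - p.e_ca);
  double i_kl  = gkl * (s.vd - p.e_k);
  double i_l   = gl * (s.vd - p.e_cl);

  s.ca += dt * (-p.ca_gain * i_hva - (s.ca - p.ca_inf) / p.ca_tau);
  if (s.ca < 1e-6) s.ca = 1e-6;

  double dvd = (-i_na - i_nap - i_km - i_kca - i_kl - i_hva - i_l
                - gc * (s.vd - s.vs) - isyn_d) / cm;
  s.vd += dt * dvd;

  // axo-somatic compartment: algebraic current balance
  tb.sna_m.step(s.vs, s.m_s);
  tb.sna_h.step(s.vs, s.h_s);
  tb.ck_n.step(s.vs, s.n_s);
  s.nap_s = nap_minf(s.vs);
  double gna = (is_py ? p.py_gna_s : p.in_gna_s) * s.m_s * s.m_s * s.m_s * s.h_s;
  double gnap = (is_py ? p.py_gnap_s : 0.0) * s.nap_s;
  double n2 = s.n_s * s.n_s;
  double gk = (is_py ? p.py_gk_s : p.in_gk_s) * n2 * n2;
  s.vs = (gc * s.vd + gna * p.e_na + gnap * p.e_na + gk * p.e_k)
         / (gc + gna + gnap + gk);
}

static inline void step_thal(ThalState& s, const Params& p, const Tables& tb,
                             bool is_tc, double gkl_scale,
                             double isyn, double dt) {
  double gna = is_tc ? p.tc_gna : p.re_gna;
  double gk = is_tc ? p.tc_gk : p.re_gk;
  double gt = is_tc ? p.tc_gt : p.re_gt;
  double gkl = (is_tc ? p.tc_gkl : p.re_gkl) * gkl_scale;
  double gl = is_tc ? p.tc_gl : p.re_gl;
  double el = is_tc ? p.tc_el : p.re_el;
  double cm = is_tc ? p.tc_cm : p.re_cm;

  if (is_tc) {
    tb.tna_m_tc.step(s.v, s.m); tb.tna_h_tc.step(s.v, s.h);
    tb.tk_n_tc.step(s.v, s.n);
    tb.tct_m.step(s.v, s.t_m); tb.tct_h.step(s.v, s.t_h);
    tb.ih_m.step(s.v, s.ih_m);
  } else {
    tb.tna_m_re.step(s.v, s.m); tb.tna_h_re.step(s.v, s.h);
    tb.tk_n_re.step(s.v, s.n);
    tb.ret_m.step(s.v, s.t_m); tb.ret_h.step(s.v, s.t_h);
  }
  double i_na = gna * s.m * s.m * s.m * s.h * (s.v - p.e_na);
  double i_k = gk * s.n * s.n * s.n * s.n * (s.v - p.e_k);
  double i_t = gt * s.t_m * s.t_m * s.t_h * (s.v - 120.0);
  double i_h = is_tc ? p.tc_gh * s.ih_m * (s.v - p.e_h) : 0.0;
  double i_kl = gkl * (s.v - p.e_k);
  double i_l = gl * (s.v - el);
  s.v += dt * (-i_na - i_k - i_kl - i_t - i_h - i_l - isyn) / cm;
}

// ---------------------------------------------------------------------------
// network

enum Receptor { R_AMPA, R_NMDA, R_GABAA, R_GABAB };

struct Projection {
  std::string name;
  int src_pop, dst_pop;            // 0 PY, 1 IN, 2 TC, 3 RE
  Receptor rec;
  bool plastic, depressing, minis;
  double mini_amp0;                // baseline mini conductance (uS)
  double gain;
  std::vector<int> src, dst;       // local (0-based) indices, by edge
  std::vector<double> w;           // per-edge conductance (uS)
  std::vector<double> mini_amp;    // per-edge mini amplitude (plastic proj)
  // CSR by source neuron
  std::vector<int> out_ptr, out_edge;
  // CSR by target neuron (for STDP in-edges)
  std::vector<int> in_ptr, in_edge;
  // aggregated postsynaptic open fractions (conductance-weighted, uS)
  std::vector<double> s;
  std::vector<double> r;           // GABAB rise stage
  void index(int n_src, int n_dst) {
    out_ptr.assign(n_src + 1, 0);
    in_ptr.assign(n_dst + 1, 0);
    for (size_t e = 0; e < src.size(); ++e) { out_ptr[src[e] + 1]++; in_ptr[dst[e] + 1]++; }
    for (int i = 0; i < n_src; ++i) out_ptr[i + 1] += out_ptr[i];
    for (int i = 0; i < n_dst; ++i) in_ptr[i + 1] += in_ptr[i];
    out_edge.resize(src.size()); in_edge.resize(src.size());
    std::vector<int> a(out_ptr.begin(), out_ptr.end()), b(in_ptr.begin(), in_ptr.end());
    for (size_t e = 0; e < src.size(); ++e) {
      out_edge[a[src[e]]++] = (int)e;
      in_edge[b[dst[e]]++] = (int)e;
    }
    s.assign(n_dst, 0.0);
    if (rec == R_GABAB) r.assign(n_dst, 0.0);
  }
};

struct MiniEvent {
  double t;
  int proj, edge;
  bool operator<(const MiniEvent& o) const { return t > o.t; }  // min-heap
};

struct Net {
  Params par;
  Tables tb;
  int n[4];                          // PY, IN, TC, RE
  std::vector<CortState> py, in_;
  std::vector<ThalState> tc, re;
  std::vector<Projection> proj;
  // last spike time per population (ms), -inf if none
  std::vector<double> last_py, last_in, last_tc, last_re;
  // short-term depression per cortical presynaptic neuron
  std::vector<double> dep_d;         // PY only (intracortical AMPA)
  std::vector<double> dep_t;
  std::priority_queue<MiniEvent> mini_q;
  std::mt19937_64 rng;
  double t = 0.0;
  int gmax_proj = -1;                // index of the plastic projection
};

static double* last_of(Net& N, int pop) {
  switch (pop) {
    case 0: return N.last_py.data();
    case 1: return N.last_in.data();
    case 2: return N.last_tc.data();
    default: return N.last_re.data();
  }
}

static void schedule_mini(Net& N, int pi, int ei) {
  std::exponential_distribution<double> ex(N.par.mini_max_rate);
  MiniEvent ev;
  ev.t = N.t + ex(N.rng);
  ev.proj = pi; ev.edge = ei;
  N.mini_q.push(ev);
}

// [[Rcpp::export]]
SEXP cpp_network_create(IntegerVector pops, List projections, List params,
                        NumericVector v0_jitter, int seed) {
  Net* N = new Net();
  N->par = read_params(params);
  for (int i = 0; i < 4; ++i) N->n[i] = pops[i];
  N->rng.seed((uint64_t)seed * 2654435761u + 12345u);
  N->py.resize(N->n[0]); N->in_.resize(N->n[1]);
  N->tc.resize(N->n[2]); N->re.resize(N->n[3]);
  int k = 0;
  for (int i = 0; i < N->n[0]; ++i) init_cort(N->py[i], -68.0 + v0_jitter[k++]);
  for (int i = 0; i < N->n[1]; ++i) init_cort(N->in_[i], -68.0 + v0_jitter[k++]);
  for (int i = 0; i < N->n[2]; ++i) init_thal(N->tc[i], -68.0 + v0_jitter[k++], N->par.tc_vt, true, 0.0);
  for (int i = 0; i < N->n[3]; ++i) init_thal(N->re[i], -68.0 + v0_jitter[k++], N->par.re_vt, false, 0.0);
  N->last_py.assign(N->n[0], -1e18); N->last_in.assign(N->n[1], -1e18);
  N->last_tc.assign(N->n[2], -1e18); N->last_re.assign(N->n[3], -1e18);
  N->dep_d.assign(N->n[0], 1.0);
  N->dep_t.assign(N->n[0], -1e18);

  for (int pi = 0; pi < projections.size(); ++pi) {
    List pr = projections[pi];
    Projection P;
    P.name = as<std::string>(pr["name"]);
    P.src_pop = as<int>(pr["src_pop"]); P.dst_pop = as<int>(pr["dst_pop"]);
    std::string rec = as<std::string>(pr["receptor"]);
    P.rec = rec == "AMPA" ? R_AMPA : rec == "NMDA" ? R_NMDA :
            rec == "GABAA" ? R_GABAA : R_GABAB;
    P.plastic = as<bool>(pr["plastic"]);
    P.depressing = as<bool>(pr["depressing"]);
    P.minis = as<bool>(pr["minis"]);
    P.mini_amp0 = as<double>(pr["mini_amp"]);
    P.gain = as<double>(pr["gain"]);
    IntegerVector s_ = pr["src"], d_ = pr["dst"];
    NumericVector w_ = pr["w"];
    P.src.assign(s_.begin(), s_.end());
    P.dst.assign(d_.begin(), d_.end());
    P.w.assign(w_.begin(), w_.end());
    P.index(N->n[P.src_pop], N->n[P.dst_pop]);
    if (P.plastic) {
      P.mini_amp.assign(P.src.size(), P.mini_amp0);
      N->gmax_proj = pi;
    }
    N->proj.push_back(std::move(P));
  }
  for (size_t pi = 0; pi < N->proj.size(); ++pi)
    if (N->proj[pi].minis)
      for (size_t e = 0; e < N->proj[pi].src.size(); ++e)
        schedule_mini(*N, (int)pi, (int)e);

  XPtr<Net> ptr(N, true);
  return ptr;
}

// depression resources of presynaptic PY neuron i at time tnow
static inline double dep_now(Net& N, int i, double tnow) {
  if (N.dep_t[i] < -1e17) return 1.0;
  double el = tnow - N.dep_t[i];
  return 1.0 - (1.0 - N.dep_d[i] * (1.0 - N.par.dep_U)) * std::exp(-el / N.par.dep_tau);
}

struct StdpRun {
  bool enabled = false;
  double a_plus, a_minus, tau_plus, tau_minus, f, g_max, mini_base;
};

// deliver spike of neuron (pop, i): synaptic release + STDP + depression
static void on_spike(Net& N, int pop, int i, double t, const StdpRun& sp) {
  double dfac = 1.0;
  if (pop == 0) {                          // presynaptic PY: use resources
    dfac = dep_now(N, i, t);
    N.dep_d[i] = dfac;
    N.dep_t[i] = t;
  }
  for (size_t pi = 0; pi < N.proj.size(); ++pi) {
    Projection& P = N.proj[pi];
    if (P.src_pop == pop) {
      double df = P.depressing ? dfac : 1.0;
      for (int q = P.out_ptr[i]; q < P.out_ptr[i + 1]; ++q) {
        int e = P.out_edge[q];
        if (P.rec == R_GABAB) P.r[P.dst[e]] += P.w[e];
        else P.s[P.dst[e]] += P.w[e] * df;
      }
    }
  }
  if (sp.enabled && N.gmax_proj >= 0) {
    Projection& P = N.proj[N.gmax_proj];
    if (pop == P.dst_pop) {               // potentiation of in-edges
      double* lasts = last_of(N, P.src_pop);
      for (int q = P.in_ptr[i]; q < P.in_ptr[i + 1]; ++q) {
        int e = P.in_edge[q];
        double tp = lasts[P.src[e]];
        if (tp > -1e17 && t > tp) {
          double dtv = t - tp;
          if (dtv < 7.0 * sp.tau_plus) {
            double F = sp.a_plus * std::exp(-dtv / sp.tau_plus);
            P.w[e] += sp.g_max * F;
            if (P.w[e] > sp.g_max) P.w[e] = sp.g_max;
            P.mini_amp[e] += sp.f * sp.mini_base * F;
          }
        }
      }
    }
    if (pop == P.src_pop) {               // depression of out-edges
      double* lastd = last_of(N, P.dst_pop);
      for (int q = P.out_ptr[i]; q < P.out_ptr[i + 1]; ++q) {
        int e = P.out_edge[q];
        double tp = lastd[P.dst[e]];
        if (tp > -1e17 && t > tp) {
          double dtv = t - tp;
          if (dtv < 7.0 * sp.tau_minus) {
            double F = sp.a_minus * std::exp(-dtv / sp.tau_minus);
            P.w[e] -= sp.g_max * F;
            if (P.w[e] < 0.0) P.w[e] = 0.0;
            P.mini_amp[e] -= sp.f * sp.mini_base * F;
            if (P.mini_amp[e] < 0.0) P.mini_amp[e] = 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_network_run(SEXP net_ptr, double duration, double dt,
                     NumericVector mod_scalars, List stdp, List stim,
                     IntegerVector record_v_ids, double record_v_dt) {
  XPtr<Net> xp(net_ptr);
  Net& N = *xp;
  Modulation M = read_mod(mod_scalars);
  N.tb.build(N.par, dt, M.ha_gh);

  StdpRun sp;
  sp.enabled = as<bool>(stdp["enabled"]);
  sp.a_plus = as<double>(stdp["a_plus"]); sp.a_minus = as<double>(stdp["a_minus"]);
  sp.tau_plus = as<double>(stdp["tau_plus"]); sp.tau_minus = as<double>(stdp["tau_minus"]);
  sp.f = as<double>(stdp["f"]); sp.g_max = as<double>(stdp["g_max"]);
  sp.mini_base = as<double>(stdp["mini_base"]);

  // stimulation events: parallel vectors (global 0-based neuron id within
  // the PY population, onset, offset, amplitude)
  IntegerVector st_id = stim["neuron"];
  NumericVector st_on = stim["onset"], st_off = stim["offset"], st_amp = stim["amp"];
  int n_ev = st_id.size(), ev_next = 0;
  // sort order assumed by onset (checked)
  for (int e = 1; e < n_ev; ++e)
    if (st_on[e] < st_on[e - 1]) stop("stimulus events must be sorted by onset");
  std::vector<double> istim(N.n[0], 0.0);
  struct ActiveStim { double off, amp; int id; };
  std::vector<ActiveStim> active;

  // per-projection decay factors and modulation scales
  std::vector<double> dec(N.proj.size()), modsc(N.proj.size());
  for (size_t pi = 0; pi < N.proj.size(); ++pi) {
    Projection& P = N.proj[pi];
    double tau = P.rec == R_AMPA ? N.par.tau_ampa :
                 P.rec == R_NMDA ? N.par.tau_nmda :
                 P.rec == R_GABAA ? N.par.tau_gabaa : N.par.gabab_tau_d;
    dec[pi] = std::exp(-dt / tau);
    double m = 1.0;
    if (P.name == "PY_PY_AMPA") m = M.ach_ampa_py;
    else if (P.name == "TC_PY_AMPA" || P.name == "TC_IN_AMPA") m = M.ach_ampa_tc;
    else if (P.name == "IN_PY_GABAA") m = M.gamma_in;
    else if (P.name == "RE_TC_GABAA" || P.name == "RE_RE_GABAA") m = M.gamma_re;
    modsc[pi] = m * P.gain;
  }
  double gabab_rdec = std::exp(-dt / N.par.gabab_tau_r);

  std::vector<double> sp_t;
  std::vector<int> sp_id;
  std::vector<double> vrec;
  std::vector<double> vrec_t;
  double next_vrec = (record_v_ids.size() > 0) ? 0.0 : 1e300;

  int nsteps = (int)std::llround(duration / dt);
  double t_end = N.t + duration;
  (void)t_end;
  int n_py = N.n[0], n_in = N.n[1], n_tc = N.n[2], n_re = N.n[3];

  std::uniform_real_distribution<double> uni(0.0, 1.0);

  for (int step = 0; step < nsteps; ++step) {
    double t = N.t + dt;

    // stimulus bookkeeping
    while (ev_next < n_ev && st_on[ev_next] <= t) {
      ActiveStim a{st_off[ev_next], st_amp[ev_next], st_id[ev_next]};
      istim[a.id] += a.amp;
      active.push_back(a);
      ++ev_next;
    }
    for (size_t a = 0; a < active.size();) {
      if (active[a].off <= t) {
        istim[active[a].id] -= active[a].amp;
        active[a] = active.back();
        active.pop_back();
      } else ++a;
    }

    // miniature releases
    while (!N.mini_q.empty() && N.mini_q.top().t <= t) {
      MiniEvent ev = N.mini_q.top(); N.mini_q.pop();
      Projection& P = N.proj[ev.proj];
      double t0 = last_of(N, P.src_pop)[P.src[ev.edge]];
      if (t0 < -1e17) t0 = 0.0;
      double frac = (ev.t > t0)
        ? (2.0 / (1.0 + std::exp(-(ev.t - t0) / N.par.mini_upsilon)) - 1.0)
        : 0.0;
      if (uni(N.rng) < frac) {
        double amp = P.plastic ? P.mini_amp[ev.edge] : P.mini_amp0;
        P.s[P.dst[ev.edge]] += amp;
      }
      double save_t = N.t; N.t = ev.t;
      schedule_mini(N, ev.proj, ev.edge);
      N.t = save_t;
    }

    // synaptic decay
    for (size_t pi = 0; pi < N.proj.size(); ++pi) {
      Projection& P = N.proj[pi];
      double d = dec[pi];
      if (P.rec == R_GABAB) {
        double rd = gabab_rdec;
        for (size_t j = 0; j < P.s.size(); ++j) {
          P.s[j] += dt * P.r[j] / N.par.gabab_tau_r;
          P.s[j] *= d;
          P.r[j] *= rd;
        }
      } else {
        for (size_t j = 0; j < P.s.size(); ++j) P.s[j] *= d;
      }
    }

    // synaptic currents per neuron (assembled per projection)
    // currents are computed against the *previous* step's voltages
    std::vector<double> icur_py(n_py, 0.0), icur_in(n_in, 0.0),
                        icur_tc(n_tc, 0.0), icur_re(n_re, 0.0);
    for (size_t pi = 0; pi < N.proj.size(); ++pi) {
      Projection& P = N.proj[pi];
      double e_rev = P.rec == R_AMPA || P.rec == R_NMDA ? N.par.e_ampa :
                     P.rec == R_GABAA ? N.par.e_gabaa : N.par.e_gabab;
      double ms = modsc[pi];
      for (int j = 0; j < (int)P.s.size(); ++j) {
        if (P.s[j] <= 1e-12) continue;
        double v, *tgt;
        switch (P.dst_pop) {
          case 0: v = N.py[j].vd; tgt = &icur_py[j]; break;
          case 1: v = N.in_[j].vd; tgt = &icur_in[j]; break;
          case 2: v = N.tc[j].v; tgt = &icur_tc[j]; break;
          default: v = N.re[j].v; tgt = &icur_re[j]; break;
        }
        double g = ms * P.s[j];
        if (P.rec == R_NMDA)
          g /= 1.0 + std::exp(-(v - N.par.mg_vhalf) / N.par.mg_k);
        *tgt += g * (v - e_rev);
      }
    }
    for (int i = 0; i < n_py; ++i) icur_py[i] -= istim[i];

    // integrate neurons, detect spikes
    for (int i = 0; i < n_py; ++i) {
      double v_prev = N.py[i].vs;
      step_cort(N.py[i], N.par, N.tb, true, M.achgkl_py, icur_py[i], dt);
      if (v_prev < N.par.spike_thresh && N.py[i].vs >= N.par.spike_thresh &&
          t - N.last_py[i] > N.par.refrac) {
        on_spike(N, 0, i, t, sp);
        N.last_py[i] = t;
        sp_t.push_back(t); sp_id.push_back(i);
      }
    }
    for (int i = 0; i < n_in; ++i) {
      double v_prev = N.in_[i].vs;
      step_cort(N.in_[i], N.par, N.tb, false, M.achgkl_in, icur_in[i], dt);
      if (v_prev < N.par.spike_thresh && N.in_[i].vs >= N.par.spike_thresh &&
          t - N.last_in[i] > N.par.refrac) {
        on_spike(N, 1, i, t, sp);
        N.last_in[i] = t;
        sp_t.push_back(t); sp_id.push_back(n_py + i);
      }
    }
    for (int i = 0; i < n_tc; ++i) {
      double v_prev = N.tc[i].v;
      step_thal(N.tc[i], N.par, N.tb, true, M.achgkl_tc, icur_tc[i], dt);
      if (v_prev < N.par.spike_thresh && N.tc[i].v >= N.par.spike_thresh &&
          t - N.last_tc[i] > N.par.refrac) {
        on_spike(N, 2, i, t, sp);
        N.last_tc[i] = t;
        sp_t.push_back(t); sp_id.push_back(n_py + n_in + i);
      }
    }
    for (int i = 0; i < n_re; ++i) {
      double v_prev = N.re[i].v;
      step_thal(N.re[i], N.par, N.tb, false, M.achgkl_re, icur_re[i], dt);
      if (v_prev < N.par.spike_thresh && N.re[i].v >= N.par.spike_thresh &&
          t - N.last_re[i] > N.par.refrac) {
        on_spike(N, 3, i, t, sp);
        N.last_re[i] = t;
        sp_t.push_back(t); sp_id.push_back(n_py + n_in + n_tc + i);
      }
    }
    N.t = t;

    if (t >= next_vrec) {
      vrec_t.push_back(t);
      for (int k = 0; k < record_v_ids.size(); ++k) {
        int id = record_v_ids[k];
        double v;
        if (id < n_py) v = N.py[id].vs;
        else if (id < n_py + n_in) v = N.in_[id - n_py].vs;
        else if (id < n_py + n_in + n_tc) v = N.tc[id - n_py - n_in].v;
        else v = N.re[id - n_py - n_in - n_tc].v;
        vrec.push_back(v);
      }
      next_vrec += record_v_dt;
    }

    if ((step & 1023) == 0) {
      // blow-up guard (checked sparsely; states are smooth at this dt)
      for (int i = 0; i < n_py; ++i)
        if (!std::isfinite(N.py[i].vd) || std::fabs(N.py[i].vd) > 500.0)
          stop("numerical blow-up at t = %.2f ms (PY neuron %d)", t, i + 1);
      Rcpp::checkUserInterrupt();
    }
  }

  List out = List::create(
    _["spike_t"] = wrap(sp_t),
    _["spike_id"] = wrap(sp_id),
    _["t_now"] = N.t);
  if (record_v_ids.size() > 0) {
    out["v_t"] = wrap(vrec_t);
    out["v"] = wrap(vrec);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_get_weights(SEXP net_ptr) {
  XPtr<Net> xp(net_ptr);
  Net& N = *xp;
  if (N.gmax_proj < 0) stop("network has no plastic projection");
  Projection& P = N.proj[N.gmax_proj];
  return List::create(
    _["src"] = wrap(P.src), _["dst"] = wrap(P.dst),
    _["w"] = wrap(P.w), _["mini_amp"] = wrap(P.mini_amp),
    _["t_now"] = N.t);
}

// ---------------------------------------------------------------------------
// isolated single-neuron runner (no synapses, no minis)

// [[Rcpp::export]]
List cpp_simulate_neuron(std::string kind, double dc, double dc_on,
                         double dc_off, double duration, double dt,
                         NumericVector mod_scalars, double record_dt,
                         List params) {
  Params p = read_params(params);
  Modulation M = read_mod(mod_scalars);
  Tables tb;
  tb.build(p, dt, M.ha_gh);
  bool cort = (kind == "PY" || kind == "IN");
  bool is_py = kind == "PY", is_tc = kind == "TC";
  CortState cs; ThalState ts;
  if (cort) init_cort(cs, -68.0);
  else init_thal(ts, -68.0, is_tc ? p.tc_vt : p.re_vt, is_tc, M.ha_gh);

  double gkl = is_py ? M.achgkl_py : kind == "IN" ? M.achgkl_in :
               is_tc ? M.achgkl_tc : M.achgkl_re;

  int nsteps = (int)std::llround(duration / dt);
  std::vector<double> tt, vv, spikes;
  double next_rec = 0.0, last_sp = -1e18;
  double t = 0.0;
  for (int s = 0; s < nsteps; ++s) {
    t += dt;
    double idc = (t >= dc_on && t < dc_off) ? -dc : 0.0;
    double v_prev = cort ? cs.vs : ts.v;
    if (cort) step_cort(cs, p, tb, is_py, gkl, idc, dt);
    else step_thal(ts, p, tb, is_tc, gkl, idc, dt);
    double v_now = cort ? cs.vs : ts.v;
    if (v_prev < p.spike_thresh && v_now >= p.spike_thresh &&
        t - last_sp > p.refrac) {
      spikes.push_back(t);
      last_sp = t;
    }
    if (t >= next_rec) {
      tt.push_back(t); vv.push_back(cort ? cs.vs : ts.v);
      next_rec += record_dt;
    }
  }
  return List::create(_["t"] = wrap(tt), _["V"] = wrap(vv),
                      _["spikes"] = wrap(spikes));
}
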