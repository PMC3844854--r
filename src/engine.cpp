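// Core simulation engine: single-compartment conductance-based GP neurons,
// double-exponential conductance synapses, calcium-gated HCN downregulation,
// adaptive Runge-Kutta-Fehlberg 4(5) integration with synaptic event handling,
// and the integrate-and-fire style STN spike-train generator.
//
// Units throughout: pF, nS, mV, ms  =>  currents in pA, rates in mV/ms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Fixed channel architecture (gate exponents per channel).
// Channels: 0 NaF, 1 NaP, 2 Kv2, 3 Kv3, 4 Kv4f, 5 Kv4s, 6 KCNQ, 7 HVA,
//           8 HCNf, 9 HCNs
// Gates (18, canonical order):
//   0 NaF.m  1 NaF.h  2 NaF.s  3 NaP.m  4 NaP.h  5 NaP.s
//   6 Kv2.m  7 Kv2.h  8 Kv3.m  9 Kv3.h 10 Kv4f.m 11 Kv4f.h
//  12 Kv4s.m 13 Kv4s.h 14 KCNQ.m 15 HVA.m 16 HCNf.m 17 HCNs.m
// ---------------------------------------------------------------------------

#define N_CHAN 10
#define N_GATE 18

static const int MU[N_CHAN]  = {3, 3, 4, 4, 4, 4, 4, 1, 1, 1};
static const int RHO[N_CHAN] = {1, 1, 1, 1, 1, 1, 0, 0, 0, 0};
static const int PHI[N_CHAN] = {1, 1, 0, 0, 0, 0, 0, 0, 0, 0};
// first gate index of each channel
static const int G0[N_CHAN]  = {0, 3, 6, 8, 10, 12, 14, 15, 16, 17};

// lookup-table range for gate kinetics
static const double TAB_VMIN = -140.0;
static const double TAB_VMAX = 90.0;
static const double TAB_DV   = 0.05;
static const int    TAB_N    = (int)((TAB_VMAX - TAB_VMIN) / TAB_DV) + 1;

static inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

struct GateKin {
  double v_half, slope, tau_min, tau_max, v_tau, sigma_tau;
  double xinf(double v) const {
    return 1.0 / (1.0 + std::exp((v_half - v) / slope));
  }
  double tau(double v) const {
    if (tau_max == tau_min) return tau_min;
    return tau_min + (tau_max - tau_min) /
      (1.0 + std::exp((v - v_tau) / sigma_tau));
  }
};

// Per-neuron state layout within the global vector:
//  [0] V, [1..18] gates, [19] Ca, [20] OG, [21] CG, [22] OA, [23] CA
#define NSV 24
#define IX_V  0
#define IX_G  1
#define IX_CA 19
#define IX_OG 20
#define IX_CG 21
#define IX_OA 22
#define IX_AC 23

struct Engine {
  int n;                                  // number of GP neurons
  double Cm, g_leak, E_leak;
  double eps, k_ca;
  std::vector<double> erev;               // per channel
  std::vector<double> g;                  // n x N_CHAN maximal conductances
  std::vector<double> ghcnf, ghcns;       // mutable HCN conductances
  // downregulation
  bool dr_enabled;
  double dr_T, dr_k, dr_theta, dr_sigma;
  // synapses
  double gab_to, gab_tc, gab_erev;
  double amp_to, amp_tc, amp_erev;
  // kinetics tables
  std::vector<double> tab_inf;            // N_GATE x TAB_N
  std::vector<double> tab_itau;           // 1/tau
  // I_ext protocol (piecewise constant, shared by all neurons)
  std::vector<double> prot_end, prot_amp;

  void build_tables(const NumericMatrix& kin) {
    tab_inf.assign(N_GATE * TAB_N, 0.0);
    tab_itau.assign(N_GATE * TAB_N, 0.0);
    for (int gi = 0; gi < N_GATE; ++gi) {
      GateKin k;
      k.v_half = kin(gi, 0); k.slope = kin(gi, 1);
      k.tau_min = kin(gi, 2); k.tau_max = kin(gi, 3);
      k.v_tau = kin(gi, 4); k.sigma_tau = kin(gi, 5);
      for (int j = 0; j < TAB_N; ++j) {
        double v = TAB_VMIN + j * TAB_DV;
        tab_inf[gi * TAB_N + j] = k.xinf(v);
        double tv = k.tau(v);
        if (tv <= 0) stop("non-positive gate time constant in kinetics table");
        tab_itau[gi * TAB_N + j] = 1.0 / tv;
      }
    }
  }

  inline void gate_lookup(int gi, double v, double& xinf, double& itau) const {
    double u = (v - TAB_VMIN) / TAB_DV;
    if (u < 0) u = 0;
    if (u > TAB_N - 1.001) u = TAB_N - 1.001;
    int j = (int)u;
    double f = u - j;
    const double* ti = &tab_inf[gi * TAB_N + j];
    const double* tt = &tab_itau[gi * TAB_N + j];
    xinf = ti[0] + f * (ti[1] - ti[0]);
    itau = tt[0] + f * (tt[1] - tt[0]);
  }

  double iext_at(double t) const {
    for (size_t i = 0; i < prot_end.size(); ++i)
      if (t < prot_end[i]) return prot_amp[i];
    return prot_end.empty() ? 0.0 : prot_amp.back();
  }

  // full right-hand side for neuron i given its state slice y -> dy
  inline void rhs_neuron(int i, const double* y, double* dy, double i_ext) const {
    double v = y[IX_V];
    double xinf[N_GATE], itau[N_GATE];
    for (int gi = 0; gi < N_GATE; ++gi)
      gate_lookup(gi, v, xinf[gi], itau[gi]);
    const double* gv = &g[i * N_CHAN];
    double isum = 0.0, ihva = 0.0;
    for (int c = 0; c < N_CHAN; ++c) {
      double gc = gv[c];
      if (c == 8) gc = ghcnf[i];
      if (c == 9) gc = ghcns[i];
      if (gc <= 0) continue;
      int base = G0[c];
      double prod = ipow(y[IX_G + base], MU[c]);
      if (RHO[c]) prod *= y[IX_G + base + 1];
      if (PHI[c]) prod *= y[IX_G + base + 2];
      double cur = prod * gc * (erev[c] - v);
      isum += cur;
      if (c == 7) ihva = cur;
    }
    // synaptic currents from aggregated (sum of g_i * state) variables
    double isyn = (y[IX_CG] - y[IX_OG]) * (gab_erev - v)
                + (y[IX_AC] - y[IX_OA]) * (amp_erev - v);
    dy[IX_V] = (g_leak * (E_leak - v) + isum + isyn + i_ext) / Cm;
    for (int gi = 0; gi < N_GATE; ++gi)
      dy[IX_G + gi] = (xinf[gi] - y[IX_G + gi]) * itau[gi];
    dy[IX_CA] = eps * (ihva - k_ca * y[IX_CA]);
    dy[IX_OG] = -y[IX_OG] / gab_to;
    dy[IX_CG] = -y[IX_CG] / gab_tc;
    dy[IX_OA] = -y[IX_OA] / amp_to;
    dy[IX_AC] = -y[IX_AC] / amp_tc;
  }

  void rhs(double t, const std::vector<double>& y, std::vector<double>& dy) const {
    double ie = iext_at(t);
    for (int i = 0; i < n; ++i)
      rhs_neuron(i, &y[i * NSV], &dy[i * NSV], ie);
  }
};

// RKF45 (Fehlberg) coefficients
static const double B21 = 1.0 / 4.0;
static const double B31 = 3.0 / 32.0, B32 = 9.0 / 32.0;
static const double B41 = 1932.0 / 2197.0, B42 = -7200.0 / 2197.0, B43 = 7296.0 / 2197.0;
static const double B51 = 439.0 / 216.0, B52 = -8.0, B53 = 3680.0 / 513.0, B54 = -845.0 / 4104.0;
static const double B61 = -8.0 / 27.0, B62 = 2.0, B63 = -3544.0 / 2565.0, B64 = 1859.0 / 4104.0, B65 = -11.0 / 40.0;
static const double C51 = 16.0 / 135.0, C53 = 6656.0 / 12825.0, C54 = 28561.0 / 56430.0, C55 = -9.0 / 50.0, C56 = 2.0 / 55.0;
static const double D1 = 25.0 / 216.0, D3 = 1408.0 / 2565.0, D4 = 2197.0 / 4104.0, D5 = -1.0 / 5.0;

struct Stepper {
  std::vector<double> k1, k2, k3, k4, k5, k6, ytmp, y5;
  void resize(size_t m) {
    k1.resize(m); k2.resize(m); k3.resize(m); k4.resize(m);
    k5.resize(m); k6.resize(m); ytmp.resize(m); y5.resize(m);
  }

  // attempt one step of size h; returns scaled error; y5 holds 5th-order result
  double step(const Engine& eng, double t, double h,
              const std::vector<double>& y) {
    size_t m = y.size();
    eng.rhs(t, const_cast<std::vector<double>&>(y), k1);
    for (size_t i = 0; i < m; ++i) ytmp[i] = y[i] + h * B21 * k1[i];
    eng.rhs(t + h / 4.0, ytmp, k2);
    for (size_t i = 0; i < m; ++i) ytmp[i] = y[i] + h * (B31 * k1[i] + B32 * k2[i]);
    eng.rhs(t + 3.0 * h / 8.0, ytmp, k3);
    for (size_t i = 0; i < m; ++i) ytmp[i] = y[i] + h * (B41 * k1[i] + B42 * k2[i] + B43 * k3[i]);
    eng.rhs(t + 12.0 * h / 13.0, ytmp, k4);
    for (size_t i = 0; i < m; ++i) ytmp[i] = y[i] + h * (B51 * k1[i] + B52 * k2[i] + B53 * k3[i] + B54 * k4[i]);
    eng.rhs(t + h, ytmp, k5);
    for (size_t i = 0; i < m; ++i) ytmp[i] = y[i] + h * (B61 * k1[i] + B62 * k2[i] + B63 * k3[i] + B64 * k4[i] + B65 * k5[i]);
    eng.rhs(t + h / 2.0, ytmp, k6);
    double errmax = 0.0;
    const double atol = 1e-5, rtol = 1e-5;  // paper's solver tolerances
    for (size_t i = 0; i < m; ++i) {
      double y5i = y[i] + h * (C51 * k1[i] + C53 * k3[i] + C54 * k4[i] + C55 * k5[i] + C56 * k6[i]);
      double y4i = y[i] + h * (D1 * k1[i] + D3 * k3[i] + D4 * k4[i] + D5 * k5[i]);
      y5[i] = y5i;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5i));
      double e = std::fabs(y5i - y4i) / sc;
      if (e > errmax) errmax = e;
    }
    return errmax;
  }
};

struct SimOutput {
  std::vector<std::vector<double> > spikes;
  std::vector<double> ca_final;
  std::vector<double> trace_t;
  std::vector<std::vector<double> > trace_v;   // per traced neuron
  std::vector<double> dr_t;
  std::vector<std::vector<double> > dr_g;      // per traced neuron (hcnf+hcns)
  long n_steps = 0, n_rejected = 0;
};

// Integrate the network from 0 to duration.  gp_* give the GP->GP adjacency
// (CSR by source), ev_*/ext_* give external (STN-like) unit events and their
// targets; ext_kind: 0 = AMPA, 1 = GABA.
static void run_sim(Engine& eng,
                    const std::vector<int>& gp_ptr,
                    const std::vector<int>& gp_tgt,
                    const std::vector<double>& gp_w,
                    const std::vector<double>& ev_time,
                    const std::vector<int>& ev_unit,
                    const std::vector<int>& ext_ptr,
                    const std::vector<int>& ext_tgt,
                    const std::vector<double>& ext_w,
                    const std::vector<int>& ext_kind,
                    double duration, double v0, double ca0,
                    double hmax, double control_dt,
                    const std::vector<int>& trace_idx, double sample_dt,
                    bool record_downreg,
                    SimOutput& out) {
  int n = eng.n;
  size_t m = (size_t)n * NSV;
  std::vector<double> y(m, 0.0), yprev(m);

  // initial conditions: V = v0, gates at steady state for v0, Ca = ca0
  for (int i = 0; i < n; ++i) {
    double* yi = &y[i * NSV];
    yi[IX_V] = v0;
    for (int gi = 0; gi < N_GATE; ++gi) {
      double xi, it;
      eng.gate_lookup(gi, v0, xi, it);
      yi[IX_G + gi] = xi;
    }
    yi[IX_CA] = ca0;
  }

  out.spikes.assign(n, std::vector<double>());
  Stepper st;
  st.resize(m);

  double t = 0.0, h = 0.01;
  const double hmin = 1e-7;
  size_t ev_i = 0;
  double next_sample = (sample_dt > 0 && !trace_idx.empty()) ? 0.0 : duration + 1.0;
  double next_control = control_dt;

  // record initial sample
  if (next_sample <= 0.0) {
    out.trace_t.push_back(0.0);
    out.trace_v.resize(trace_idx.size());
    for (size_t q = 0; q < trace_idx.size(); ++q)
      out.trace_v[q].push_back(y[trace_idx[q] * NSV + IX_V]);
    next_sample = sample_dt;
  } else if (!trace_idx.empty()) {
    out.trace_v.resize(trace_idx.size());
  }
  if (record_downreg && !trace_idx.empty()) {
    out.dr_g.resize(2 * trace_idx.size());
    out.dr_t.push_back(0.0);
    for (size_t q = 0; q < trace_idx.size(); ++q) {
      out.dr_g[2 * q].push_back(eng.ghcnf[trace_idx[q]]);
      out.dr_g[2 * q + 1].push_back(eng.ghcns[trace_idx[q]]);
    }
  }

  while (t < duration - 1e-9) {
    // next hard stop: control boundary, external event, protocol edge, end
    double tstop = std::min(next_control, duration);
    if (ev_i < ev_time.size()) tstop = std::min(tstop, ev_time[ev_i]);
    for (size_t pi = 0; pi < eng.prot_end.size(); ++pi)
      if (eng.prot_end[pi] > t + 1e-9) { tstop = std::min(tstop, eng.prot_end[pi]); break; }

    // integrate to `tstop`
    while (t < tstop - 1e-9) {
      double hs = std::min(h, std::min(hmax, tstop - t));
      double err;
      for (;;) {
        err = st.step(eng, t, hs, y);
        if (err <= 1.0 || hs <= hmin) break;
        double fac = std::max(0.2, 0.9 * std::pow(err, -0.25));
        hs = std::max(hmin, hs * fac);
        out.n_rejected++;
      }
      if (err > 1.0 && hs <= hmin)
        stop("integration failure: error control cannot be satisfied at t = %f", t);
      yprev = y;
      y = st.y5;
      double tnew = t + hs;
      out.n_steps++;

      // clamp gates/calcium; guard operating range
      for (int i = 0; i < n; ++i) {
        double* yi = &y[i * NSV];
        for (int gi = 0; gi < N_GATE; ++gi) {
          if (yi[IX_G + gi] < 0) yi[IX_G + gi] = 0;
          if (yi[IX_G + gi] > 1) yi[IX_G + gi] = 1;
        }
        if (yi[IX_CA] < 0) yi[IX_CA] = 0;
        if (yi[IX_V] < -150.0 || yi[IX_V] > 90.0 || !std::isfinite(yi[IX_V]))
          stop("membrane potential of neuron %d left the operating range at t = %f ms (V = %f)",
               i + 1, tnew, yi[IX_V]);
      }

      // spike detection: upward 0 mV crossing, linear interpolation
      for (int i = 0; i < n; ++i) {
        double va = yprev[i * NSV + IX_V], vb = y[i * NSV + IX_V];
        if (va < 0.0 && vb >= 0.0) {
          double ts = t + hs * (0.0 - va) / (vb - va);
          out.spikes[i].push_back(ts);
          // GP->GP synaptic increments (applied at end of the accepted step)
          for (int e = gp_ptr[i]; e < gp_ptr[i + 1]; ++e) {
            double* yt = &y[gp_tgt[e] * NSV];
            yt[IX_OG] += gp_w[e];
            yt[IX_CG] += gp_w[e];
          }
        }
      }

      // trace sampling by linear interpolation inside the step
      while (next_sample <= tnew + 1e-12 && next_sample <= duration + 1e-12) {
        double f = (next_sample - t) / hs;
        out.trace_t.push_back(next_sample);
        for (size_t q = 0; q < trace_idx.size(); ++q) {
          double va = yprev[trace_idx[q] * NSV + IX_V];
          double vb = y[trace_idx[q] * NSV + IX_V];
          out.trace_v[q].push_back(va + f * (vb - va));
        }
        next_sample += sample_dt;
      }

      t = tnew;
      if (err > 1e-12) {
        double fac = std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
        h = std::min(hmax, hs * fac);
      } else h = std::min(hmax, hs * 5.0);
    }
    t = tstop;

    // external unit events at exactly this time
    while (ev_i < ev_time.size() && ev_time[ev_i] <= t + 1e-9) {
      int u = ev_unit[ev_i];
      for (int e = ext_ptr[u]; e < ext_ptr[u + 1]; ++e) {
        double* yt = &y[ext_tgt[e] * NSV];
        if (ext_kind[e] == 0) { yt[IX_OA] += ext_w[e]; yt[IX_AC] += ext_w[e]; }
        else                  { yt[IX_OG] += ext_w[e]; yt[IX_CG] += ext_w[e]; }
      }
      ev_i++;
    }

    // control boundary: HCN downregulation applied between solves
    if (t >= next_control - 1e-9) {
      if (eng.dr_enabled) {
        for (int i = 0; i < n; ++i) {
          double ca = y[i * NSV + IX_CA];
          if (ca > eng.dr_T) {
            double dec = eng.dr_k * control_dt /
              (1.0 + std::exp((eng.dr_theta - ca) / eng.dr_sigma));
            eng.ghcnf[i] = std::max(0.0, eng.ghcnf[i] - dec);
            eng.ghcns[i] = std::max(0.0, eng.ghcns[i] - dec);
          }
        }
      }
      if (record_downreg && !trace_idx.empty()) {
        out.dr_t.push_back(t);
        for (size_t q = 0; q < trace_idx.size(); ++q) {
          out.dr_g[2 * q].push_back(eng.ghcnf[trace_idx[q]]);
          out.dr_g[2 * q + 1].push_back(eng.ghcns[trace_idx[q]]);
        }
      }
      next_control += control_dt;
    }
  }
  out.ca_final.assign(n, 0.0);
  for (int i = 0; i < n; ++i) out.ca_final[i] = y[i * NSV + IX_CA];
}


// ---------------------------------------------------------------------------
// Windowed network integration.  GP neurons are coupled only through spike
// events, so within one control window (1 ms) every neuron's ODE system is
// independent and is integrated with its own adaptive step.  External (STN)
// events are delivered at their exact times inside the window; GP-spike
// synaptic increments are exchanged at window boundaries (a delivery latency
// of at most one control interval, comparable to a physiological synaptic
// delay).  HCN downregulation is applied between windows.
// ---------------------------------------------------------------------------

struct NeuronEvent { double t; double w; int kind; };

static void run_sim_windowed(Engine& eng,
                             const std::vector<int>& gp_ptr,
                             const std::vector<int>& gp_tgt,
                             const std::vector<double>& gp_w,
                             const std::vector<double>& ev_time,
                             const std::vector<int>& ev_unit,
                             const std::vector<int>& ext_ptr,
                             const std::vector<int>& ext_tgt,
                             const std::vector<double>& ext_w,
                             const std::vector<int>& ext_kind,
                             double duration, double v0, double ca0,
                             double hmax, double control_dt,
                             const std::vector<int>& trace_idx,
                             double sample_dt,
                             bool record_downreg,
                             SimOutput& out) {
  int n = eng.n;
  // per-neuron external event lists (exact in-window delivery)
  std::vector<std::vector<NeuronEvent> > nev(n);
  for (size_t e = 0; e < ev_time.size(); ++e) {
    int u = ev_unit[e];
    for (int k = ext_ptr[u]; k < ext_ptr[u + 1]; ++k) {
      NeuronEvent ne;
      ne.t = ev_time[e]; ne.w = ext_w[k]; ne.kind = ext_kind[k];
      nev[ext_tgt[k]].push_back(ne);
    }
  }
  // ev_time is sorted, so each per-neuron list is sorted too
  std::vector<size_t> nev_i(n, 0);

  std::vector<double> y((size_t)n * NSV), h(n, 0.01);
  for (int i = 0; i < n; ++i) {
    double* yi = &y[i * NSV];
    for (int k = 0; k < NSV; ++k) yi[k] = 0.0;
    yi[IX_V] = v0;
    for (int gi = 0; gi < N_GATE; ++gi) {
      double xi, it;
      eng.gate_lookup(gi, v0, xi, it);
      yi[IX_G + gi] = xi;
    }
    yi[IX_CA] = ca0;
  }
  out.spikes.assign(n, std::vector<double>());

  std::vector<int> trace_pos(n, -1);
  for (size_t q = 0; q < trace_idx.size(); ++q) trace_pos[trace_idx[q]] = q;
  bool tracing = !trace_idx.empty() && sample_dt > 0;
  if (tracing) out.trace_v.resize(trace_idx.size());
  if (record_downreg && !trace_idx.empty())
    out.dr_g.resize(2 * trace_idx.size());

  Engine eng1 = eng;          // single-neuron view sharing tables
  eng1.n = 1;
  Stepper st;
  st.resize(NSV);
  std::vector<double> y1(NSV), yprev(NSV);
  std::vector<double> pend_og(n, 0.0), pend_cg(n, 0.0);

  long n_win = (long)std::ceil(duration / control_dt - 1e-9);
  double next_sample = 0.0;
  const double hmin = 1e-7;

  // record initial samples
  if (tracing) {
    out.trace_t.push_back(0.0);
    for (size_t q = 0; q < trace_idx.size(); ++q)
      out.trace_v[q].push_back(y[trace_idx[q] * NSV + IX_V]);
    next_sample = sample_dt;
  }
  if (record_downreg && !trace_idx.empty()) {
    out.dr_t.push_back(0.0);
    for (size_t q = 0; q < trace_idx.size(); ++q) {
      out.dr_g[2 * q].push_back(eng.ghcnf[trace_idx[q]]);
      out.dr_g[2 * q + 1].push_back(eng.ghcns[trace_idx[q]]);
    }
  }

  double win_sample_start = next_sample;
  for (long w = 0; w < n_win; ++w) {
    double t0w = w * control_dt;
    double t1w = std::min(duration, (w + 1) * control_dt);
    double first_sample_in_win = win_sample_start;

    for (int i = 0; i < n; ++i) {
      double* yi = &y[i * NSV];
      // pending GP-spike increments from the previous window
      yi[IX_OG] += pend_og[i]; pend_og[i] = 0.0;
      yi[IX_CG] += pend_cg[i]; pend_cg[i] = 0.0;
      std::copy(yi, yi + NSV, y1.begin());
      eng1.g.assign(eng.g.begin() + i * N_CHAN,
                    eng.g.begin() + (i + 1) * N_CHAN);
      eng1.ghcnf.assign(1, eng.ghcnf[i]);
      eng1.ghcns.assign(1, eng.ghcns[i]);
      double t = t0w;
      double hi = h[i];
      double nsamp = first_sample_in_win;
      while (t < t1w - 1e-9) {
        // next stop: external event for this neuron, protocol edge, window end
        double tstop = t1w;
        while (nev_i[i] < nev[i].size() && nev[i][nev_i[i]].t <= t + 1e-9) {
          // deliver events at (or before) current time
          const NeuronEvent& ne = nev[i][nev_i[i]];
          if (ne.kind == 0) { y1[IX_OA] += ne.w; y1[IX_AC] += ne.w; }
          else              { y1[IX_OG] += ne.w; y1[IX_CG] += ne.w; }
          nev_i[i]++;
        }
        if (nev_i[i] < nev[i].size() && nev[i][nev_i[i]].t < tstop)
          tstop = nev[i][nev_i[i]].t;
        for (size_t pi = 0; pi < eng.prot_end.size(); ++pi)
          if (eng.prot_end[pi] > t + 1e-9) {
            if (eng.prot_end[pi] < tstop) tstop = eng.prot_end[pi];
            break;
          }
        while (t < tstop - 1e-9) {
          double hs = std::min(hi, std::min(hmax, tstop - t));
          double err;
          for (;;) {
            err = st.step(eng1, t, hs, y1);
            if (err <= 1.0 || hs <= hmin) break;
            double fac = std::max(0.2, 0.9 * std::pow(err, -0.25));
            hs = std::max(hmin, hs * fac);
            out.n_rejected++;
          }
          if (err > 1.0 && hs <= hmin)
            stop("integration failure at t = %f (neuron %d)", t, i + 1);
          std::copy(y1.begin(), y1.end(), yprev.begin());
          std::copy(st.y5.begin(), st.y5.end(), y1.begin());
          out.n_steps++;
          for (int gi = 0; gi < N_GATE; ++gi) {
            if (y1[IX_G + gi] < 0) y1[IX_G + gi] = 0;
            if (y1[IX_G + gi] > 1) y1[IX_G + gi] = 1;
          }
          if (y1[IX_CA] < 0) y1[IX_CA] = 0;
          if (y1[IX_V] < -150.0 || y1[IX_V] > 90.0 || !std::isfinite(y1[IX_V]))
            stop("membrane potential of neuron %d left the operating range at t = %f ms (V = %f)",
                 i + 1, t + hs, y1[IX_V]);
          double tnew = t + hs;
          if (yprev[IX_V] < 0.0 && y1[IX_V] >= 0.0) {
            double ts = t + hs * (0.0 - yprev[IX_V]) / (y1[IX_V] - yprev[IX_V]);
            out.spikes[i].push_back(ts);
            for (int e = gp_ptr[i]; e < gp_ptr[i + 1]; ++e) {
              pend_og[gp_tgt[e]] += gp_w[e];
              pend_cg[gp_tgt[e]] += gp_w[e];
            }
          }
          if (tracing && trace_pos[i] >= 0) {
            while (nsamp <= tnew + 1e-12 && nsamp <= duration + 1e-12) {
              double f = (nsamp - t) / hs;
              out.trace_v[trace_pos[i]].push_back(
                yprev[IX_V] + f * (y1[IX_V] - yprev[IX_V]));
              nsamp += sample_dt;
            }
          }
          t = tnew;
          if (err > 1e-12) {
            double fac = std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
            hi = std::min(hmax, hs * fac);
          } else hi = std::min(hmax, hs * 5.0);
        }
        t = tstop;
      }
      h[i] = hi;
      std::copy(y1.begin(), y1.end(), yi);
      eng.ghcnf[i] = eng1.ghcnf[0];
      eng.ghcns[i] = eng1.ghcns[0];
    }
    // advance the shared sample clock
    if (tracing) {
      while (win_sample_start <= t1w + 1e-12 &&
             win_sample_start <= duration + 1e-12) {
        out.trace_t.push_back(win_sample_start);
        win_sample_start += sample_dt;
      }
    }
    // downregulation between windows
    if (eng.dr_enabled) {
      for (int i = 0; i < n; ++i) {
        double ca = y[i * NSV + IX_CA];
        if (ca > eng.dr_T) {
          double dec = eng.dr_k * control_dt /
            (1.0 + std::exp((eng.dr_theta - ca) / eng.dr_sigma));
          eng.ghcnf[i] = std::max(0.0, eng.ghcnf[i] - dec);
          eng.ghcns[i] = std::max(0.0, eng.ghcns[i] - dec);
        }
      }
    }
    if (record_downreg && !trace_idx.empty()) {
      out.dr_t.push_back(t1w);
      for (size_t q = 0; q < trace_idx.size(); ++q) {
        out.dr_g[2 * q].push_back(eng.ghcnf[trace_idx[q]]);
        out.dr_g[2 * q + 1].push_back(eng.ghcns[trace_idx[q]]);
      }
    }
    if (w % 256 == 0) Rcpp::checkUserInterrupt();
  }
  out.ca_final.assign(n, 0.0);
  for (int i = 0; i < n; ++i) out.ca_final[i] = y[i * NSV + IX_CA];
}

static Engine make_engine(const NumericMatrix& gmat,
                          const NumericVector& membrane,
                          const NumericVector& erev,
                          const NumericMatrix& kinetics,
                          const NumericVector& calcium,
                          const NumericVector& downreg,
                          const NumericVector& syn_gaba,
                          const NumericVector& syn_ampa) {
  if (gmat.ncol() != N_CHAN) stop("conductance matrix must have 10 columns");
  if (kinetics.nrow() != N_GATE || kinetics.ncol() != 6)
    stop("kinetics matrix must be 18 x 6");
  Engine eng;
  eng.n = gmat.nrow();
  eng.Cm = membrane[0]; eng.g_leak = membrane[1]; eng.E_leak = membrane[2];
  eng.eps = calcium[0]; eng.k_ca = calcium[1];
  eng.erev.assign(erev.begin(), erev.end());
  eng.g.resize((size_t)eng.n * N_CHAN);
  eng.ghcnf.resize(eng.n); eng.ghcns.resize(eng.n);
  for (int i = 0; i < eng.n; ++i) {
    for (int c = 0; c < N_CHAN; ++c) eng.g[i * N_CHAN + c] = gmat(i, c);
    eng.ghcnf[i] = gmat(i, 8);
    eng.ghcns[i] = gmat(i, 9);
  }
  eng.dr_enabled = downreg[0] != 0.0;
  eng.dr_T = downreg[1]; eng.dr_k = downreg[2];
  eng.dr_theta = downreg[3]; eng.dr_sigma = downreg[4];
  eng.gab_to = syn_gaba[0]; eng.gab_tc = syn_gaba[1]; eng.gab_erev = syn_gaba[2];
  eng.amp_to = syn_ampa[0]; eng.amp_tc = syn_ampa[1]; eng.amp_erev = syn_ampa[2];
  eng.build_tables(kinetics);
  return eng;
}

// [[Rcpp::export]]
List cpp_simulate_network(NumericMatrix gmat,
                          NumericVector membrane,
                          NumericVector erev,
                          NumericMatrix kinetics,
                          NumericVector calcium,
                          NumericVector downreg,
                          NumericVector syn_gaba,
                          NumericVector syn_ampa,
                          IntegerVector gp_ptr, IntegerVector gp_tgt, NumericVector gp_w,
                          NumericVector ev_time, IntegerVector ev_unit,
                          IntegerVector ext_ptr, IntegerVector ext_tgt,
                          NumericVector ext_w, IntegerVector ext_kind,
                          NumericVector prot_end, NumericVector prot_amp,
                          double duration, double v0, double ca0,
                          double hmax, double control_dt,
                          IntegerVector trace_idx, double sample_dt,
                          bool record_downreg) {
  Engine eng = make_engine(gmat, membrane, erev, kinetics, calcium, downreg,
                           syn_gaba, syn_ampa);
  eng.prot_end.assign(prot_end.begin(), prot_end.end());
  eng.prot_amp.assign(prot_amp.begin(), prot_amp.end());

  std::vector<int> gpp(gp_ptr.begin(), gp_ptr.end());
  std::vector<int> gpt(gp_tgt.begin(), gp_tgt.end());
  std::vector<double> gpw(gp_w.begin(), gp_w.end());
  std::vector<double> evt(ev_time.begin(), ev_time.end());
  std::vector<int> evu(ev_unit.begin(), ev_unit.end());
  std::vector<int> exp_(ext_ptr.begin(), ext_ptr.end());
  std::vector<int> ext(ext_tgt.begin(), ext_tgt.end());
  std::vector<double> exw(ext_w.begin(), ext_w.end());
  std::vector<int> exk(ext_kind.begin(), ext_kind.end());
  std::vector<int> tri(trace_idx.begin(), trace_idx.end());

  SimOutput out;
  run_sim_windowed(eng, gpp, gpt, gpw, evt, evu, exp_, ext, exw, exk,
                   duration, v0, ca0, hmax, control_dt, tri, sample_dt,
                   record_downreg, out);

  List spikes(eng.n);
  for (int i = 0; i < eng.n; ++i) spikes[i] = wrap(out.spikes[i]);
  NumericMatrix ghcn(eng.n, 2);
  for (int i = 0; i < eng.n; ++i) {
    ghcn(i, 0) = eng.ghcnf[i];
    ghcn(i, 1) = eng.ghcns[i];
  }
  List res = List::create(
    _["spikes"] = spikes,
    _["ghcn_final"] = ghcn,
    _["ca_final"] = wrap(out.ca_final),
    _["n_steps"] = (double)out.n_steps,
    _["n_rejected"] = (double)out.n_rejected);
  if (!tri.empty() && sample_dt > 0) {
    NumericMatrix tv(out.trace_t.size(), tri.size());
    for (size_t q = 0; q < tri.size(); ++q)
      for (size_t r = 0; r < out.trace_t.size(); ++r)
        tv(r, q) = out.trace_v[q][r];
    res["trace_t"] = wrap(out.trace_t);
    res["trace_v"] = tv;
  }
  if (record_downreg && !tri.empty()) {
    NumericMatrix dg(out.dr_t.size(), 2 * tri.size());
    for (size_t q = 0; q < 2 * tri.size(); ++q)
      for (size_t r = 0; r < out.dr_t.size(); ++r)
        dg(r, q) = out.dr_g[q][r];
    res["downreg_t"] = wrap(out.dr_t);
    res["downreg_g"] = dg;
  }
  return res;
}

// Simulate each neuron of a population in isolation (no synapses), each with
// its own adaptive time step.  Shared I_ext protocol.
// [[Rcpp::export]]
List cpp_simulate_population(NumericMatrix gmat,
                             NumericVector membrane,
                             NumericVector erev,
                             NumericMatrix kinetics,
                             NumericVector calcium,
                             NumericVector downreg,
                             NumericVector syn_gaba,
                             NumericVector syn_ampa,
                             NumericVector prot_end, NumericVector prot_amp,
                             double duration, double v0, double ca0,
                             double hmax, double control_dt,
                             IntegerVector trace_idx, double sample_dt) {
  int n = gmat.nrow();
  Engine base = make_engine(gmat, membrane, erev, kinetics, calcium, downreg,
                            syn_gaba, syn_ampa);
  base.prot_end.assign(prot_end.begin(), prot_end.end());
  base.prot_amp.assign(prot_amp.begin(), prot_amp.end());

  std::vector<bool> want_trace(n, false);
  for (int q = 0; q < trace_idx.size(); ++q) want_trace[trace_idx[q]] = true;

  std::vector<int> noptr(2, 0);
  std::vector<int> noi;
  std::vector<double> nod;
  std::vector<int> ptr1(1, 0);

  List spikes(n);
  List traces(trace_idx.size());
  NumericMatrix ghcn(n, 2);
  NumericVector ca_final(n);
  int tq = 0;
  for (int i = 0; i < n; ++i) {
    Engine eng = base;            // copies tables; cheap relative to the solve
    eng.n = 1;
    std::vector<double> g1(base.g.begin() + i * N_CHAN,
                           base.g.begin() + (i + 1) * N_CHAN);
    eng.g = g1;
    eng.ghcnf.assign(1, base.ghcnf[i]);
    eng.ghcns.assign(1, base.ghcns[i]);
    std::vector<int> tri;
    if (want_trace[i]) tri.push_back(0);
    SimOutput out;
    std::vector<double> noev;
    std::vector<int> noevu;
    run_sim(eng, noptr, noi, nod, noev, noevu, ptr1, noi, nod, noi,
            duration, v0, ca0, hmax, control_dt, tri,
            want_trace[i] ? sample_dt : 0.0, false, out);
    spikes[i] = wrap(out.spikes[0]);
    ghcn(i, 0) = eng.ghcnf[0];
    ghcn(i, 1) = eng.ghcns[0];
    ca_final[i] = out.ca_final[0];
    if (want_trace[i]) {
      traces[tq++] = List::create(_["t"] = wrap(out.trace_t),
                                  _["v"] = wrap(out.trace_v[0]));
    }
    if (i % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["spikes"] = spikes,
                      _["ghcn_final"] = ghcn,
                      _["ca_final"] = ca_final,
                      _["traces"] = traces);
}

// ---------------------------------------------------------------------------
// STN spike-train generator: leaky accumulator with exponentially decaying
// threshold, Gaussian noise and an absolute refractory period.  Drive is
// piecewise constant over windows (active / inactive SWA phases).
// Uses R's RNG so that set.seed() governs reproducibility.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_stn_train(NumericVector w_end, NumericVector w_drive,
                            double tau_m, double tau_th,
                            double theta0, double theta_jump,
                            double noise_sd, double refractory,
                            double dt) {
  RNGScope scope;
  double duration = w_end[w_end.size() - 1];
  long nsteps = (long)std::ceil(duration / dt);
  std::vector<double> out;
  double v = 0.0, th = theta0, t_last = -1e18;
  size_t wi = 0;
  double sq = noise_sd * std::sqrt(dt);
  for (long s = 0; s < nsteps; ++s) {
    double t = s * dt;
    while (wi < (size_t)w_end.size() - 1 && t >= w_end[wi]) wi++;
    double D = w_drive[wi];
    v += dt * (D - v) / tau_m + sq * norm_rand();
    th += dt * (theta0 - th) / tau_th;
    if (v >= th && (t - t_last) >= refractory) {
      out.push_back(t + dt);
      t_last = t + dt;
      v = 0.0;
      th = theta0 + theta_jump;
    }
  }
  return wrap(out);
}
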