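// Compartmental conductance-based neuron integrator.
//
// Scheme: staggered theta-method (default theta = 0.5, Crank-Nicolson) for the
// voltage equation on the compartment tree (Hines-ordered direct solve),
// Rush-Larsen exponential updates for Hodgkin-Huxley gates (tabulated rates),
// backward-Euler master-equation updates for Markov channels (conserves total
// occupancy exactly and preserves non-negativity unconditionally), and an
// exact linear update for the calcium shell.
//
// Units: mV, ms, nF, uS, nA, mM, cm^2. Current sign convention: outward > 0.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double CA_R = 8.314462618;   // J/(mol K)
static const double CA_F = 96485.33212;   // C/mol

// ---------------------------------------------------------------------------
// gate rate forms
// form 1: exp     A * exp((v - V0)/K)
// form 2: sigmoid A / (1 + exp((v - V0)/K))
// form 3: linoid  A * (v - V0) / (exp((v - V0)/K) - 1)
static inline double rate_form(int form, double A, double V0, double K, double v) {
  double x = (v - V0) / K;
  switch (form) {
  case 1: return A * std::exp(x);
  case 2: return A / (1.0 + std::exp(x));
  case 3:
    if (std::fabs(x) < 1e-6) return A * K * (1.0 - 0.5 * x);
    return A * (v - V0) / (std::exp(x) - 1.0);
  default: stop("unknown rate form");
  }
  return 0.0;
}

// gate encodings (NumericVector):
// type 1 (alpha/beta):  [1, p, fa, Aa, V0a, Ka, fb, Ab, V0b, Kb]
// type 2 (minf/tau):    [2, p, vhalf, k, taumin, tauamp, vt, k1, k2]
//        minf = 1/(1+exp(-(v-vhalf)/k)); tau = taumin + tauamp /
//               (exp((v-vt)/k1) + exp(-(v-vt)/k2))
// type 3 (Ca-dependent, Gabbiani form):
//        [3, p, Aa, Ba, Ka, Ab, Bb, Kb]
//        alpha = Aa / (1 + Ka*exp(-v/Ba)/ca); beta = Ab / (1 + ca/(Kb*exp(-v/Bb)))
static void gate_minf_tau(const double *g, double v, double ca,
                          double &minf, double &tau) {
  int type = (int)g[0];
  if (type == 1) {
    double a = rate_form((int)g[2], g[3], g[4], g[5], v);
    double b = rate_form((int)g[6], g[7], g[8], g[9], v);
    double s = a + b;
    if (s <= 0) { minf = 0.0; tau = 1e9; return; }
    minf = a / s; tau = 1.0 / s;
  } else if (type == 2) {
    minf = 1.0 / (1.0 + std::exp(-(v - g[2]) / g[3]));
    tau  = g[4] + g[5] / (std::exp((v - g[6]) / g[7]) + std::exp(-(v - g[6]) / g[8]));
  } else if (type == 3) {
    double a = g[2] / (1.0 + g[4] * std::exp(-v / g[3]) / ca);
    double b = g[5] / (1.0 + ca / (g[6] * std::exp(-v / g[7])));
    double s = a + b;
    minf = a / s; tau = 1.0 / s;
  } else stop("unknown gate type");
  if (tau < 1e-6) tau = 1e-6;
}

// [[Rcpp::export]]
List cpp_gate_minf_tau(NumericVector gate, NumericVector v, double ca) {
  int n = v.size();
  NumericVector minf(n), tau(n);
  for (int i = 0; i < n; ++i) {
    if (!R_finite(v[i])) stop("non-finite membrane potential");
    double m, t;
    gate_minf_tau(REAL(gate), v[i], ca, m, t);
    minf[i] = m; tau[i] = t;
  }
  return List::create(_["minf"] = minf, _["tau"] = tau);
}

// ---------------------------------------------------------------------------
// 13-state Markov (resurgent Na) scheme.
// states: C1..C5 = 0..4, O = 5, OB = 6, I1..I6 = 7..12
// params: [alpha0, va, beta0, vb, gamma, delta, epsilon, zeta0, vz,
//          Con, Coff, Oon, Ooff, scale]
static const int MK_N = 13;

static void markov_rates(const double *p, double v, double *Q /*13x13 row-major*/) {
  double s = p[13];
  double al = s * p[0] * std::exp(v / p[1]);
  double be = s * p[2] * std::exp(-v / p[3]);
  double ga = s * p[4], de = s * p[5], ep = s * p[6];
  double ze = s * p[7] * std::exp(-v / p[8]);
  double Con = s * p[9], Coff = s * p[10], Oon = s * p[11], Ooff = s * p[12];
  double a = std::pow(p[11] / p[9], 0.25);
  double b = std::pow(p[12] / p[10], 0.25);
  for (int i = 0; i < MK_N * MK_N; ++i) Q[i] = 0.0;
  auto add = [&](int f, int t, double r) {
    Q[f * MK_N + t] += r; Q[f * MK_N + f] -= r;
  };
  // closed chain
  add(0, 1, 4 * al); add(1, 0, be);
  add(1, 2, 3 * al); add(2, 1, 2 * be);
  add(2, 3, 2 * al); add(3, 2, 3 * be);
  add(3, 4, al);     add(4, 3, 4 * be);
  add(4, 5, ga);     add(5, 4, de);
  // open <-> blocked
  add(5, 6, ep);     add(6, 5, ze);
  // inactivated chain
  add(7, 8, 4 * al * a);  add(8, 7, be * b);
  add(8, 9, 3 * al * a);  add(9, 8, 2 * be * b);
  add(9, 10, 2 * al * a); add(10, 9, 3 * be * b);
  add(10, 11, al * a);    add(11, 10, 4 * be * b);
  add(11, 12, ga);        add(12, 11, de);
  // closed <-> inactivated, open <-> I6
  for (int i = 0; i < 5; ++i) {
    add(i, i + 7, Con * std::pow(a, i));
    add(i + 7, i, Coff * std::pow(b, i));
  }
  add(5, 12, Oon); add(12, 5, Ooff);
}

// [[Rcpp::export]]
NumericMatrix cpp_markov_q(NumericVector params, double v) {
  std::vector<double> Q(MK_N * MK_N);
  markov_rates(REAL(params), v, Q.data());
  NumericMatrix out(MK_N, MK_N);
  for (int i = 0; i < MK_N; ++i)
    for (int j = 0; j < MK_N; ++j) out(i, j) = Q[i * MK_N + j];
  return out;
}

// backward-Euler step of dP/dt = Q^T P: solve (I - dt Q^T) P' = P
static void markov_be(const double *Q, double dt, double *P) {
  double A[MK_N * MK_N], r[MK_N];
  for (int i = 0; i < MK_N; ++i) {
    r[i] = P[i];
    for (int j = 0; j < MK_N; ++j)
      A[i * MK_N + j] = (i == j ? 1.0 : 0.0) - dt * Q[j * MK_N + i];
  }
  // Gaussian elimination, no pivoting (diagonally dominant M-matrix)
  for (int k = 0; k < MK_N; ++k) {
    double d = A[k * MK_N + k];
    for (int i = k + 1; i < MK_N; ++i) {
      double f = A[i * MK_N + k] / d;
      if (f == 0.0) continue;
      for (int j = k; j < MK_N; ++j) A[i * MK_N + j] -= f * A[k * MK_N + j];
      r[i] -= f * r[k];
    }
  }
  for (int i = MK_N - 1; i >= 0; --i) {
    double s = r[i];
    for (int j = i + 1; j < MK_N; ++j) s -= A[i * MK_N + j] * P[j];
    P[i] = s / A[i * MK_N + i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_markov_step(NumericVector params, NumericVector occ,
                              double v, double dt) {
  if (occ.size() != MK_N) stop("occupancy must have 13 states");
  std::vector<double> Q(MK_N * MK_N);
  markov_rates(REAL(params), v, Q.data());
  NumericVector out = clone(occ);
  markov_be(Q.data(), dt, REAL(out));
  return out;
}

// ---------------------------------------------------------------------------
// full model simulation

struct GateState {
  int chan;           // owner channel
  int p;              // exponent
  bool tabulated;     // types 1/2 are tabulated; type 3 evaluated directly
  const double *spec; // encoding vector
  std::vector<double> minf_tab, efac_tab; // over voltage grid
  double m;           // state
};

struct Chan {
  int comp;
  double gbar;        // uS
  double erev;        // mV (ignored if erev_ca)
  bool erev_ca;
  bool carries_ca;
  std::vector<int> gates; // indices into gate array
  int markov;         // index into markov array or -1
};

struct Markov {
  int chan;
  const double *par;
  double P[MK_N];
};

struct CaPool {
  int comp;
  double cao, carest, beta, depth_um, floorv, ca, eca, temp_K;
};

static const double TAB_VMIN = -120.0, TAB_VMAX = 80.0, TAB_DV = 0.05;
static const int TAB_N = (int)((TAB_VMAX - TAB_VMIN) / TAB_DV) + 1;

static inline double nernst_ca(double cao, double cai, double temp_K) {
  return 1000.0 * CA_R * temp_K / (2.0 * CA_F) * std::log(cao / cai);
}

// [[Rcpp::export]]
List cpp_simulate(List model, List control) {
  // ---- parse model
  IntegerVector parent = model["parent"];        // 0-based, -1 root, parent[i] < i
  NumericVector cm = model["cm_nf"];
  NumericVector ga = model["ga_us"];
  NumericVector area = model["area_cm2"];
  double v_init = as<double>(model["v_init"]);
  List chans = model["channels"];
  int ncomp = parent.size(), nchan = chans.size();

  std::vector<Chan> C(nchan);
  std::vector<GateState> G;
  std::vector<Markov> M;
  std::vector<NumericVector> gate_specs; // keep protected
  std::vector<NumericVector> mk_specs;
  for (int c = 0; c < nchan; ++c) {
    List ch = chans[c];
    C[c].comp = as<int>(ch["comp"]);
    C[c].gbar = as<double>(ch["gbar_us"]);
    C[c].erev = as<double>(ch["erev"]);
    C[c].erev_ca = as<bool>(ch["erev_ca"]);
    C[c].carries_ca = as<bool>(ch["carries_ca"]);
    C[c].markov = -1;
    List gl = ch["gates"];
    for (int g = 0; g < gl.size(); ++g) {
      NumericVector gv = gl[g];
      gate_specs.push_back(gv);
      GateState gs;
      gs.chan = c;
      gs.p = (int)gv[1];
      gs.tabulated = ((int)gv[0] != 3);
      gs.spec = REAL(gate_specs.back());
      gs.m = 0.0;
      C[c].gates.push_back((int)G.size());
      G.push_back(gs);
    }
    if (!Rf_isNull(ch["markov"])) {
      NumericVector mp = ch["markov"];
      mk_specs.push_back(mp);
      Markov mk;
      mk.chan = c;
      mk.par = REAL(mk_specs.back());
      for (int i = 0; i < MK_N; ++i) mk.P[i] = 0.0;
      mk.P[0] = 1.0;
      C[c].markov = (int)M.size();
      M.push_back(mk);
    }
  }
  // fix spec pointers (vector reallocation above invalidates nothing since we
  // stored NumericVector copies; refresh pointers to be safe)
  {
    int gi = 0, mi = 0;
    for (int c = 0; c < nchan; ++c) {
      List ch = chans[c];
      List gl = ch["gates"];
      for (int g = 0; g < gl.size(); ++g) G[C[c].gates[g]].spec = REAL(gate_specs[gi++]);
      if (C[c].markov >= 0) M[C[c].markov].par = REAL(mk_specs[mi++]);
    }
  }

  std::vector<CaPool> pools;
  std::vector<int> pool_of(ncomp, -1);
  if (!Rf_isNull(model["capools"])) {
    List cps = model["capools"];
    for (int i = 0; i < cps.size(); ++i) {
      List cp = cps[i];
      CaPool p;
      p.comp = as<int>(cp["comp"]);
      p.cao = as<double>(cp["cao"]);
      p.carest = as<double>(cp["carest"]);
      p.beta = as<double>(cp["beta"]);
      p.depth_um = as<double>(cp["depth_um"]);
      p.floorv = as<double>(cp["floor"]);
      p.temp_K = as<double>(cp["temp_K"]);
      p.ca = p.carest;
      p.eca = nernst_ca(p.cao, p.ca, p.temp_K);
      pool_of[p.comp] = (int)pools.size();
      pools.push_back(p);
    }
  }

  // ---- parse control
  double dt = as<double>(control["dt"]);
  double theta = as<double>(control["theta"]);
  double settle_ms = as<double>(control["settle_ms"]);
  double t_stop = as<double>(control["t_stop"]);
  double record_dt = as<double>(control["record_dt"]);
  IntegerVector rec_comps = control["record_comps"];
  bool rec_ca = as<bool>(control["record_ca"]);
  bool rec_cur = as<bool>(control["record_currents"]);
  int inj_comp = as<int>(control["inj_comp"]);
  int stim_mode = as<int>(control["stim_mode"]);
  double st_on = as<double>(control["stim_onset"]);
  double st_off = as<double>(control["stim_offset"]);
  double st_amp = as<double>(control["stim_amp_na"]);
  NumericVector stim_vec = control["stim_vec"];
  int clamp_comp = as<int>(control["clamp_comp"]);
  NumericVector clamp_v = control["clamp_v"]; // per step, NaN = free

  int nsteps = (int)std::lround(t_stop / dt);
  int rstride = (int)std::lround(record_dt / dt);
  if (rstride < 1) rstride = 1;
  int nrec = nsteps / rstride + 1;

  // ---- build rate tables for tabulated gates (minf + exp(-dt/tau))
  for (size_t g = 0; g < G.size(); ++g) {
    if (!G[g].tabulated) continue;
    G[g].minf_tab.resize(TAB_N);
    G[g].efac_tab.resize(TAB_N);
    for (int i = 0; i < TAB_N; ++i) {
      double v = TAB_VMIN + i * TAB_DV, m, tau;
      gate_minf_tau(G[g].spec, v, 1e-4, m, tau);
      G[g].minf_tab[i] = m;
      G[g].efac_tab[i] = std::exp(-dt / tau);
    }
  }

  // ---- init state
  std::vector<double> V(ncomp, v_init), Vnew(ncomp), Gsum(ncomp), GEsum(ncomp);
  for (size_t g = 0; g < G.size(); ++g) {
    double ca = 1e-4, m, tau;
    int pc = pool_of[C[G[g].chan].comp];
    if (pc >= 0) ca = pools[pc].ca;
    gate_minf_tau(G[g].spec, v_init, ca, m, tau);
    G[g].m = m;
  }
  // Markov channels: relax to stationary occupancy at v_init
  for (size_t k = 0; k < M.size(); ++k) {
    double Q[MK_N * MK_N];
    markov_rates(M[k].par, v_init, Q);
    for (int it = 0; it < 400; ++it) markov_be(Q, 5.0, M[k].P);
  }

  // ---- outputs
  NumericVector t_out(nrec);
  NumericMatrix v_out(nrec, rec_comps.size());
  NumericMatrix ca_out(rec_ca ? nrec : 0, rec_ca ? (int)pools.size() : 0);
  NumericMatrix cur_out(rec_cur ? nrec : 0, rec_cur ? nchan : 0);
  NumericVector iclamp_out(clamp_comp >= 0 ? nrec : 0);
  double occ_err_max = 0.0;

  std::vector<double> d(ncomp), rhs(ncomp), gprod(nchan), Jv(ncomp);

  int total_steps = (int)std::lround(settle_ms / dt) + nsteps;
  int settle_steps = (int)std::lround(settle_ms / dt);
  int rec_i = 0;

  auto record_state = [&](int ridx, double tval, double iclamp) {
    t_out[ridx] = tval;
    for (int j = 0; j < rec_comps.size(); ++j) v_out(ridx, j) = V[rec_comps[j]];
    if (rec_ca) for (size_t p = 0; p < pools.size(); ++p) ca_out(ridx, p) = pools[p].ca;
    if (rec_cur) {
      for (int c = 0; c < nchan; ++c) {
        double gp = 1.0;
        for (size_t gi = 0; gi < C[c].gates.size(); ++gi) {
          double m = G[C[c].gates[gi]].m;
          for (int e = 0; e < G[C[c].gates[gi]].p; ++e) gp *= m;
        }
        if (C[c].markov >= 0) gp = M[C[c].markov].P[5];
        double E = C[c].erev_ca ? pools[pool_of[C[c].comp]].eca : C[c].erev;
        cur_out(ridx, c) = C[c].gbar * gp * (V[C[c].comp] - E);
      }
    }
    if (clamp_comp >= 0) iclamp_out[ridx] = iclamp;
  };

  double iclamp_cur = NA_REAL;
  if (settle_steps == 0) record_state(rec_i++, 0.0, NA_REAL);

  for (int step = 0; step < total_steps; ++step) {
    bool settling = step < settle_steps;
    int pstep = step - settle_steps;           // protocol step index
    double t_mid = (pstep + 0.5) * dt;

    // stimulus (nA)
    double inj = 0.0;
    if (!settling) {
      if (stim_mode == 1) {
        if (t_mid >= st_on && t_mid < st_off) inj = st_amp;
      } else if (stim_mode == 2 && pstep < stim_vec.size()) {
        inj = stim_vec[pstep];
      }
    }

    // clamp target for this step
    double vc = NA_REAL;
    bool clamped = false;
    if (!settling && clamp_comp >= 0 && pstep < clamp_v.size() && R_finite(clamp_v[pstep])) {
      vc = clamp_v[pstep];
      clamped = true;
    }

    // staggered (leapfrog) gate updates: gates advance from t - dt/2 to
    // t + dt/2 using V(t), so the voltage solve over [t, t+dt] sees
    // conductances centered at t + dt/2 (second-order accurate)
    for (size_t g = 0; g < G.size(); ++g) {
      int comp = C[G[g].chan].comp;
      double vu = V[comp];
      if (G[g].tabulated) {
        double x = (vu - TAB_VMIN) / TAB_DV;
        if (x < 0) x = 0;
        if (x > TAB_N - 1.001) x = TAB_N - 1.001;
        int i0 = (int)x;
        double w = x - i0;
        double minf = G[g].minf_tab[i0] * (1 - w) + G[g].minf_tab[i0 + 1] * w;
        double efac = G[g].efac_tab[i0] * (1 - w) + G[g].efac_tab[i0 + 1] * w;
        G[g].m = minf + (G[g].m - minf) * efac;
      } else {
        double ca = pools[pool_of[comp]].ca, m, tau;
        gate_minf_tau(G[g].spec, vu, ca, m, tau);
        G[g].m = m + (G[g].m - m) * std::exp(-dt / tau);
      }
      if (G[g].m < 0) G[g].m = 0;
      if (G[g].m > 1) G[g].m = 1;
    }
    for (size_t k = 0; k < M.size(); ++k) {
      int comp = C[M[k].chan].comp;
      double Q[MK_N * MK_N];
      markov_rates(M[k].par, V[comp], Q);
      markov_be(Q, dt, M[k].P);
      double s = 0.0;
      for (int i = 0; i < MK_N; ++i) s += M[k].P[i];
      double err = std::fabs(s - 1.0);
      if (err > occ_err_max) occ_err_max = err;
    }

    // conductances with the (mid-step) gate states
    std::fill(Gsum.begin(), Gsum.end(), 0.0);
    std::fill(GEsum.begin(), GEsum.end(), 0.0);
    for (int c = 0; c < nchan; ++c) {
      double gp = 1.0;
      for (size_t gi = 0; gi < C[c].gates.size(); ++gi) {
        double m = G[C[c].gates[gi]].m;
        for (int e = 0; e < G[C[c].gates[gi]].p; ++e) gp *= m;
      }
      if (C[c].markov >= 0) gp = M[C[c].markov].P[5];
      double g = C[c].gbar * gp;
      gprod[c] = g;
      double E = C[c].erev_ca ? pools[pool_of[C[c].comp]].eca : C[c].erev;
      Gsum[C[c].comp] += g;
      GEsum[C[c].comp] += g * E;
    }

    // J(V) = ionic + axial current at old voltages
    for (int i = 0; i < ncomp; ++i) Jv[i] = Gsum[i] * V[i] - GEsum[i];
    for (int i = 1; i < ncomp; ++i) {
      double f = ga[i] * (V[i] - V[parent[i]]);
      Jv[i] += f;
      Jv[parent[i]] -= f;
    }

    // assemble theta-method system
    for (int i = 0; i < ncomp; ++i) {
      d[i] = cm[i] / dt + theta * Gsum[i];
      rhs[i] = cm[i] / dt * V[i] - (1.0 - theta) * Jv[i] + theta * GEsum[i];
    }
    if (inj != 0.0) rhs[inj_comp] += inj;
    for (int i = 1; i < ncomp; ++i) {
      d[i] += theta * ga[i];
      d[parent[i]] += theta * ga[i];
    }

    // Hines solve (parent[i] < i)
    for (int i = ncomp - 1; i >= 1; --i) {
      int p = parent[i];
      if (clamped && i == clamp_comp) { rhs[p] += theta * ga[i] * vc; continue; }
      if (clamped && p == clamp_comp) continue;
      double f = theta * ga[i] / d[i];
      d[p] -= f * theta * ga[i];
      rhs[p] += f * rhs[i];
    }
    Vnew[0] = (clamped && clamp_comp == 0) ? vc : rhs[0] / d[0];
    for (int i = 1; i < ncomp; ++i) {
      if (clamped && i == clamp_comp) { Vnew[i] = vc; continue; }
      Vnew[i] = (rhs[i] + theta * ga[i] * Vnew[parent[i]]) / d[i];
    }
    for (int i = 0; i < ncomp; ++i)
      if (!R_finite(Vnew[i]))
        stop("integration diverged (non-finite V) at t = %.3f ms in compartment %d",
             settling ? -(settle_ms - (step + 1) * dt) : (pstep + 1) * dt, i + 1);

    // clamp electrode current (nA): capacitive + theta-weighted ionic/axial
    if (clamped || (clamp_comp >= 0)) {
      double Jc_new = Gsum[clamp_comp] * Vnew[clamp_comp] - GEsum[clamp_comp];
      double Jc_old = Jv[clamp_comp];
      for (int i = 1; i < ncomp; ++i) {
        if (i == clamp_comp) Jc_new += ga[i] * (Vnew[i] - Vnew[parent[i]]);
        else if (parent[i] == clamp_comp) Jc_new -= ga[i] * (Vnew[i] - Vnew[clamp_comp]);
      }
      iclamp_cur = cm[clamp_comp] * (Vnew[clamp_comp] - V[clamp_comp]) / dt +
        theta * Jc_new + (1.0 - theta) * Jc_old;
    }

    // calcium pools: I_Ca from updated gates at new voltage
    for (size_t p = 0; p < pools.size(); ++p) {
      double ica_na = 0.0;
      for (int c = 0; c < nchan; ++c) {
        if (!C[c].carries_ca || C[c].comp != pools[p].comp) continue;
        double gp = 1.0;
        for (size_t gi = 0; gi < C[c].gates.size(); ++gi) {
          double m = G[C[c].gates[gi]].m;
          for (int e = 0; e < G[C[c].gates[gi]].p; ++e) gp *= m;
        }
        if (C[c].markov >= 0) gp = M[C[c].markov].P[5];
        ica_na += C[c].gbar * gp * (Vnew[pools[p].comp] - pools[p].eca);
      }
      double ica_ma_cm2 = ica_na * 1e-6 / area[pools[p].comp];
      double depth_cm = pools[p].depth_um * 1e-4;
      double influx = -ica_ma_cm2 / (2.0 * CA_F * depth_cm); // mM/ms
      double css = pools[p].carest + influx / pools[p].beta;
      pools[p].ca = css + (pools[p].ca - css) * std::exp(-pools[p].beta * dt);
      if (pools[p].ca < pools[p].floorv) pools[p].ca = pools[p].floorv;
      pools[p].eca = nernst_ca(pools[p].cao, pools[p].ca, pools[p].temp_K);
    }

    V = Vnew;

    if (step == settle_steps - 1)
      record_state(rec_i++, 0.0, NA_REAL);
    else if (!settling && (pstep + 1) % rstride == 0 && rec_i < nrec)
      record_state(rec_i++, (pstep + 1) * dt, iclamp_cur);
  }

  return List::create(
    _["time"] = t_out,
    _["v"] = v_out,
    _["ca"] = ca_out,
    _["currents"] = cur_out,
    _["i_clamp"] = iclamp_out,
    _["occ_err_max"] = occ_err_max);
}
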