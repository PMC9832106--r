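// Closed-loop 0D circulation with a two-lobe hepatic sub-circuit.
//
// Ten volume states (mL): right atrium, right ventricle, pulmonary
// compartment, left atrium, left ventricle, systemic arteries,
// portal/splanchnic venous compartment, right liver lobe, left liver
// lobe, vena cava.  Heart chambers are time-varying elastances
// E(t) = Eb + Ea * e(t) with a piecewise-cosine activation; valves are
// ideal diodes with a smooth (softplus-like) regularization.  All flow
// balances are antisymmetric, so total volume is conserved exactly by
// the integrator up to round-off.
//
// Fixed-step classical RK4; the regularized valve laws keep the system
// non-stiff at the default step (smallest time constant ~ R_valve/E_max
// ~ 2 ms >> dt).  A fixed step also gives bit-identical reproducibility.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pars {
  // time-varying elastances (mmHg/mL)
  double Ea_RA, Eb_RA, Ea_RV, Eb_RV, Ea_LA, Eb_LA, Ea_LV, Eb_LV;
  // valve + fixed resistances (mmHg s/mL)
  double R_tri, R_pul, R_mit, R_aor, R_pulm, R_vr, R_OO, R_DO;
  // lobar hepatic resistances (post-resection values; <=0 => branch removed)
  double R_pv_R, R_pv_L, R_ha_R, R_ha_L, R_hv_R, R_hv_L;
  // compliances (mL/mmHg)
  double C_pa, C_sa, C_pv, C_liv_R, C_liv_L, C_vc;
  // unstressed volumes (mL), state order
  double V0[10];
  // timing (s)
  double T, t_vent_dur, t_atr_on, t_atr_dur;
  double eps_valve;
  bool lobe_R, lobe_L;
};

inline double activation(double t, double T, double t_on, double dur) {
  double tau = t - t_on;
  tau -= T * std::floor(tau / T);
  if (tau >= dur) return 0.0;
  return 0.5 * (1.0 - std::cos(2.0 * M_PI * tau / dur));
}

// smooth positive part: (x + sqrt(x^2 + eps^2)) / 2
inline double spos(double x, double eps) {
  return 0.5 * (x + std::sqrt(x * x + eps * eps));
}

struct Flows {
  double tri, pul, pulm, mit, aor, oo, dojl, pv_R, pv_L, ha_R, ha_L,
      hv_R, hv_L, vr;
  double P[10];
};

inline void rhs(double t, const double *V, const Pars &p, double *dV,
                Flows *fl = nullptr) {
  const double ev = activation(t, p.T, 0.0, p.t_vent_dur);
  const double ea = activation(t, p.T, p.t_atr_on, p.t_atr_dur);

  const double P_ra = (p.Eb_RA + p.Ea_RA * ea) * (V[0] - p.V0[0]);
  const double P_rv = (p.Eb_RV + p.Ea_RV * ev) * (V[1] - p.V0[1]);
  const double P_pa = (V[2] - p.V0[2]) / p.C_pa;
  const double P_la = (p.Eb_LA + p.Ea_LA * ea) * (V[3] - p.V0[3]);
  const double P_lv = (p.Eb_LV + p.Ea_LV * ev) * (V[4] - p.V0[4]);
  const double P_sa = (V[5] - p.V0[5]) / p.C_sa;
  const double P_pv = (V[6] - p.V0[6]) / p.C_pv;
  const double P_lr = (V[7] - p.V0[7]) / p.C_liv_R;
  const double P_ll = (V[8] - p.V0[8]) / p.C_liv_L;
  const double P_vc = (V[9] - p.V0[9]) / p.C_vc;

  const double Q_tri = spos(P_ra - P_rv, p.eps_valve) / p.R_tri;
  const double Q_pul = spos(P_rv - P_pa, p.eps_valve) / p.R_pul;
  const double Q_pulm = (P_pa - P_la) / p.R_pulm;
  const double Q_mit = spos(P_la - P_lv, p.eps_valve) / p.R_mit;
  const double Q_aor = spos(P_lv - P_sa, p.eps_valve) / p.R_aor;
  const double Q_oo = (P_sa - P_vc) / p.R_OO;
  const double Q_do = (P_sa - P_pv) / p.R_DO;
  const double Q_pv_R = p.lobe_R ? (P_pv - P_lr) / p.R_pv_R : 0.0;
  const double Q_pv_L = p.lobe_L ? (P_pv - P_ll) / p.R_pv_L : 0.0;
  const double Q_ha_R = p.lobe_R ? (P_sa - P_lr) / p.R_ha_R : 0.0;
  const double Q_ha_L = p.lobe_L ? (P_sa - P_ll) / p.R_ha_L : 0.0;
  const double Q_hv_R = p.lobe_R ? (P_lr - P_vc) / p.R_hv_R : 0.0;
  const double Q_hv_L = p.lobe_L ? (P_ll - P_vc) / p.R_hv_L : 0.0;
  const double Q_vr = (P_vc - P_ra) / p.R_vr;

  dV[0] = Q_vr - Q_tri;
  dV[1] = Q_tri - Q_pul;
  dV[2] = Q_pul - Q_pulm;
  dV[3] = Q_pulm - Q_mit;
  dV[4] = Q_mit - Q_aor;
  dV[5] = Q_aor - Q_oo - Q_do - Q_ha_R - Q_ha_L;
  dV[6] = Q_do - Q_pv_R - Q_pv_L;
  dV[7] = Q_pv_R + Q_ha_R - Q_hv_R;
  dV[8] = Q_pv_L + Q_ha_L - Q_hv_L;
  dV[9] = Q_oo + Q_hv_R + Q_hv_L - Q_vr;

  if (fl) {
    fl->tri = Q_tri; fl->pul = Q_pul; fl->pulm = Q_pulm; fl->mit = Q_mit;
    fl->aor = Q_aor; fl->oo = Q_oo; fl->dojl = Q_do;
    fl->pv_R = Q_pv_R; fl->pv_L = Q_pv_L; fl->ha_R = Q_ha_R;
    fl->ha_L = Q_ha_L; fl->hv_R = Q_hv_R; fl->hv_L = Q_hv_L; fl->vr = Q_vr;
    fl->P[0] = P_ra; fl->P[1] = P_rv; fl->P[2] = P_pa; fl->P[3] = P_la;
    fl->P[4] = P_lv; fl->P[5] = P_sa; fl->P[6] = P_pv; fl->P[7] = P_lr;
    fl->P[8] = P_ll; fl->P[9] = P_vc;
  }
}

inline void rk4_step(double t, double dt, double *V, const Pars &p) {
  double k1[10], k2[10], k3[10], k4[10], tmp[10];
  rhs(t, V, p, k1);
  for (int i = 0; i < 10; ++i) tmp[i] = V[i] + 0.5 * dt * k1[i];
  rhs(t + 0.5 * dt, tmp, p, k2);
  for (int i = 0; i < 10; ++i) tmp[i] = V[i] + 0.5 * dt * k2[i];
  rhs(t + 0.5 * dt, tmp, p, k3);
  for (int i = 0; i < 10; ++i) tmp[i] = V[i] + dt * k3[i];
  rhs(t + dt, tmp, p, k4);
  for (int i = 0; i < 10; ++i)
    V[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

Pars unpack(const NumericVector &pv) {
  Pars p;
  p.Ea_RA = pv["Ea_RA"]; p.Eb_RA = pv["Eb_RA"];
  p.Ea_RV = pv["Ea_RV"]; p.Eb_RV = pv["Eb_RV"];
  p.Ea_LA = pv["Ea_LA"]; p.Eb_LA = pv["Eb_LA"];
  p.Ea_LV = pv["Ea_LV"]; p.Eb_LV = pv["Eb_LV"];
  p.R_tri = pv["R_tri"]; p.R_pul = pv["R_pul"];
  p.R_mit = pv["R_mit"]; p.R_aor = pv["R_aor"];
  p.R_pulm = pv["R_pulm"]; p.R_vr = pv["R_vr"];
  p.R_OO = pv["R_OO"]; p.R_DO = pv["R_DO"];
  p.R_pv_R = pv["R_pv_R"]; p.R_pv_L = pv["R_pv_L"];
  p.R_ha_R = pv["R_ha_R"]; p.R_ha_L = pv["R_ha_L"];
  p.R_hv_R = pv["R_hv_R"]; p.R_hv_L = pv["R_hv_L"];
  p.C_pa = pv["C_pa"]; p.C_sa = pv["C_sa"]; p.C_pv = pv["C_pv"];
  p.C_liv_R = pv["C_liv_R"]; p.C_liv_L = pv["C_liv_L"]; p.C_vc = pv["C_vc"];
  const char *v0n[10] = {"V0_ra", "V0_rv", "V0_pa", "V0_la", "V0_lv",
                         "V0_sa", "V0_pv", "V0_liv_R", "V0_liv_L", "V0_vc"};
  for (int i = 0; i < 10; ++i) p.V0[i] = pv[v0n[i]];
  p.T = pv["T"]; p.t_vent_dur = pv["t_vent_dur"];
  p.t_atr_on = pv["t_atr_on"]; p.t_atr_dur = pv["t_atr_dur"];
  p.eps_valve = pv["eps_valve"];
  p.lobe_R = p.R_pv_R > 0.0;
  p.lobe_L = p.R_pv_L > 0.0;
  return p;
}

} // namespace

// Simulate whole cardiac cycles until the six cycle-averaged clinical
// outputs (P_pv, PCG, MAP, CO, Q_ha, Q_pv) are cycle-to-cycle stationary
// (max relative change < tol) or max_cycles is reached.  Returns the
// per-cycle output history, the final state, and (optionally) a
// resampled trace of the last cycle.
// [[Rcpp::export(name = ".cpp_simulate_cycles")]]
List cpp_simulate_cycles(NumericVector pars, NumericVector state0,
                         double dt, int max_cycles, double tol,
                         int trace_stride) {
  Pars p = unpack(pars);
  const int nsteps = std::max(8, (int)std::lround(p.T / dt));
  const double h = p.T / nsteps; // align steps with the period exactly

  double V[10];
  for (int i = 0; i < 10; ++i) V[i] = state0[i];

  NumericMatrix cyc_out(max_cycles, 7); // P_pv PCG MAP CO Q_ha Q_pv P_vc
  bool converged = false;
  int ncyc = 0;
  double resid = NA_REAL;

  const bool want_trace = trace_stride > 0;
  const int ntr = want_trace ? nsteps / trace_stride + 1 : 0;
  NumericMatrix tr_vol(std::max(ntr, 1), 10), tr_prs(std::max(ntr, 1), 10),
      tr_flw(std::max(ntr, 1), 14);
  NumericVector tr_time(std::max(ntr, 1));

  double prev[6] = {0, 0, 0, 0, 0, 0};

  for (int c = 0; c < max_cycles; ++c) {
    double acc_ppv = 0, acc_pvc = 0, acc_psa = 0, acc_qaor = 0,
           acc_qha = 0, acc_qpv = 0;
    const bool last_chance = want_trace; // record every cycle, keep last
    int k = 0;
    for (int s = 0; s < nsteps; ++s) {
      const double t = s * h;
      Flows fl;
      double dV[10];
      rhs(t, V, p, dV, &fl);
      acc_ppv += fl.P[6]; acc_pvc += fl.P[9]; acc_psa += fl.P[5];
      acc_qaor += fl.aor; acc_qha += fl.ha_R + fl.ha_L;
      acc_qpv += fl.pv_R + fl.pv_L;
      if (last_chance && s % trace_stride == 0 && k < ntr) {
        tr_time[k] = t;
        for (int i = 0; i < 10; ++i) {
          tr_vol(k, i) = V[i];
          tr_prs(k, i) = fl.P[i];
        }
        tr_flw(k, 0) = fl.tri; tr_flw(k, 1) = fl.pul; tr_flw(k, 2) = fl.pulm;
        tr_flw(k, 3) = fl.mit; tr_flw(k, 4) = fl.aor; tr_flw(k, 5) = fl.oo;
        tr_flw(k, 6) = fl.dojl; tr_flw(k, 7) = fl.pv_R; tr_flw(k, 8) = fl.pv_L;
        tr_flw(k, 9) = fl.ha_R; tr_flw(k, 10) = fl.ha_L;
        tr_flw(k, 11) = fl.hv_R; tr_flw(k, 12) = fl.hv_L; tr_flw(k, 13) = fl.vr;
        ++k;
      }
      rk4_step(t, h, V, p);
      if (!std::isfinite(V[0]) || !std::isfinite(V[9]))
        stop("integration failure: non-finite state at cycle %d", c + 1);
    }
    const double mppv = acc_ppv / nsteps, mpvc = acc_pvc / nsteps;
    const double out[6] = {mppv, mppv - mpvc, acc_psa / nsteps,
                           acc_qaor / nsteps * 0.06, // mL/s -> L/min
                           acc_qha / nsteps * 0.06, acc_qpv / nsteps * 0.06};
    cyc_out(c, 0) = out[0]; cyc_out(c, 1) = out[1]; cyc_out(c, 2) = out[2];
    cyc_out(c, 3) = out[3]; cyc_out(c, 4) = out[4]; cyc_out(c, 5) = out[5];
    cyc_out(c, 6) = mpvc;
    ncyc = c + 1;
    if (c > 0) {
      double r = 0;
      for (int i = 0; i < 6; ++i) {
        const double sc = std::max(std::fabs(prev[i]), 1e-8);
        r = std::max(r, std::fabs(out[i] - prev[i]) / sc);
      }
      resid = r;
      if (r < tol) { converged = true; }
    }
    for (int i = 0; i < 6; ++i) prev[i] = out[i];
    if (converged) break;
  }

  NumericVector fin(10);
  for (int i = 0; i < 10; ++i) fin[i] = V[i];

  List out = List::create(
      _["cycle_outputs"] = cyc_out(Range(0, ncyc - 1), Range(0, 6)),
      _["converged"] = converged, _["cycles"] = ncyc,
      _["residual"] = resid, _["final_state"] = fin,
      _["nsteps"] = nsteps, _["dt"] = h);
  if (want_trace) {
    out["trace_time"] = tr_time;
    out["trace_volumes"] = tr_vol;
    out["trace_pressures"] = tr_prs;
    out["trace_flows"] = tr_flw;
  }
  return out;
}
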