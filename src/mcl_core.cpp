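// Fixed-step integration core for the mock-loop circuit.
//
// The readable model definition lives in R (circuit_rhs); this file is the
// fast path and must stay numerically identical to it.  Parameter slot
// order is shared with .pack_params() in R/params.R — change both together.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

enum ParSlot {
  HR, SYS_FRAC, N1, N2, TAU1, TAU2, HILL_K,
  EMAX_LV, EMIN_LV, V0_LV, PCAP_LV,
  EMAX_RV, EMIN_RV, V0_RV, PCAP_RV,
  A_RL, A_LR, A_SAT, PERI_ON, PERI_K, PERI_V0,
  R_MI, R_AO, R_TRI, R_PV,
  R_UB, R_LB, R_PULM, R_VR, R_PVEN, CLAMP,
  C_LA, V0_LA, C_RA, V0_RA,
  AOC_A, AOC_P, AOC_W,
  SVC_A, SVC_P, SVC_W,
  PAC_A, PAC_P, PAC_W,
  PVC_A, PVC_P, PVC_W,
  E_ON, E_SPD, E_RET, E_C0, E_C1, E_C2, E_RD, E_RR, E_L,
  P_ATM, NPAR
};

static const int NSTATE = 9;
// recorded columns: time + 9 states + 8 pressures + 5 valve/loop flows + e_norm
static const int NOUT = 24;

static inline double hill_elastance(double t, const double *p) {
  double T = 60.0 / p[HR];
  double x = t / T;
  x -= std::floor(x);
  double a = std::pow(x / p[TAU1], p[N1]);
  double b = std::pow(x / p[TAU2], p[N2]);
  return p[HILL_K] * (a / (1.0 + a)) / (1.0 + b);
}

static inline double chamber_p(double w, double air_ref, double p_abs_ref,
                               double w_ref, double p_atm, bool *ok) {
  double air = air_ref - (w - w_ref);
  if (air <= 0.0) { *ok = false; return 0.0; }
  return p_abs_ref * air_ref / air - p_atm;
}

// Evaluates the node-balance RHS.  `out`, when non-NULL, receives the
// recorded auxiliary quantities (pressures/flows) at (t, y).
static bool rhs(double t, const double *y, const double *p,
                double *dy, double *out) {
  bool ok = true;
  const double en = hill_elastance(t, p);
  // pneumatic-driver saturation: active pressure cannot exceed the driver
  // line pressure scaled by the activation waveform
  const double act_lv = std::min((p[EMAX_LV] - p[EMIN_LV]) * (y[0] - p[V0_LV]),
                                 p[PCAP_LV]);
  const double act_rv = std::min((p[EMAX_RV] - p[EMIN_RV]) * (y[1] - p[V0_RV]),
                                 p[PCAP_RV]);
  const double p_lv_free = p[EMIN_LV] * (y[0] - p[V0_LV]) + en * act_lv;
  const double p_rv_free = p[EMIN_RV] * (y[1] - p[V0_RV]) + en * act_rv;
  double p_peri = 0.0;
  if (p[PERI_ON] > 0.5) {
    double excess = y[0] + y[1] + y[2] + y[3] - p[PERI_V0];
    if (excess > 0.0) p_peri = p[PERI_K] * excess;
  }
  // septal cross-talk saturates: the transmitted pressure is clipped at
  // +/- A_SAT (septal displacement limit)
  const double sat = p[A_SAT];
  const double x_rv = std::max(-sat, std::min(sat, p_rv_free));
  const double x_lv = std::max(-sat, std::min(sat, p_lv_free));
  const double p_lv = p_lv_free + p[A_RL] * x_rv + p_peri;
  const double p_rv = p_rv_free + p[A_LR] * x_lv + p_peri;

  const double p_la = (y[2] - p[V0_LA]) / p[C_LA];
  const double p_ra = (y[3] - p[V0_RA]) / p[C_RA];

  const double p_ao  = chamber_p(y[4], p[AOC_A], p[AOC_P], p[AOC_W], p[P_ATM], &ok);
  const double p_svc = chamber_p(y[5], p[SVC_A], p[SVC_P], p[SVC_W], p[P_ATM], &ok);
  const double p_pa  = chamber_p(y[6], p[PAC_A], p[PAC_P], p[PAC_W], p[P_ATM], &ok);
  const double p_pvc = chamber_p(y[7], p[PVC_A], p[PVC_P], p[PVC_W], p[P_ATM], &ok);
  if (!ok) return false;

  // ideal-diode valves
  const double q_mi   = std::max(0.0, p_la - p_lv) / p[R_MI];
  const double q_av   = std::max(0.0, p_lv - p_ao) / p[R_AO];
  const double q_tri  = std::max(0.0, p_ra - p_rv) / p[R_TRI];
  const double q_pval = std::max(0.0, p_rv - p_pa) / p[R_PV];

  const bool ecmo_on = p[E_ON] > 0.5;
  const bool retro = p[E_RET] > 0.5;
  const double q_e = ecmo_on ? y[8] : 0.0;
  const double q_fem_in = (ecmo_on && retro) ? q_e : 0.0;

  // systemic branches; the lower-body branch has a massless femoral
  // mid-node where retrograde ECMO return enters
  const double q_ub = (p_ao - p_svc) / p[R_UB];
  const double r_half = 0.5 * p[R_LB];
  const double p_fem = 0.5 * (p_ao + p_svc + q_fem_in * r_half);
  const double q_lb1 = (p_ao - p_fem) / r_half;
  const double q_lb2 = (p_fem - p_svc) / r_half;

  const double q_vr   = (p_svc - p_ra) / (p[R_VR] * p[CLAMP]);
  const double q_part = (p_pa - p_pvc) / p[R_PULM];
  const double q_pven = (p_pvc - p_la) / p[R_PVEN];

  double dq_e = 0.0;
  if (ecmo_on) {
    const double q_lmin = q_e * 0.06;
    const double head = p[E_C0] * p[E_SPD] * p[E_SPD]
      + p[E_C1] * p[E_SPD] * q_lmin + p[E_C2] * q_lmin * q_lmin;
    const double p_ret = retro ? p_fem : p_ao;
    dq_e = (p_ra + head - p_ret - (p[E_RD] + p[E_RR]) * q_e) / p[E_L];
  }

  dy[0] = q_mi - q_av;
  dy[1] = q_tri - q_pval;
  dy[2] = q_pven - q_mi;
  dy[3] = q_vr - q_tri - q_e;
  dy[4] = q_av - q_ub - q_lb1 + ((ecmo_on && !retro) ? q_e : 0.0);
  dy[5] = q_ub + q_lb2 - q_vr;
  dy[6] = q_pval - q_part;
  dy[7] = q_part - q_pven;
  dy[8] = dq_e;

  if (out) {
    out[0] = t;
    for (int i = 0; i < NSTATE; ++i) out[1 + i] = y[i];
    out[10] = p_lv;  out[11] = p_rv;  out[12] = p_la; out[13] = p_ra;
    out[14] = p_ao;  out[15] = p_svc; out[16] = p_pa; out[17] = p_pvc;
    out[18] = q_mi;  out[19] = q_av;  out[20] = q_tri;
    out[21] = q_pval; out[22] = q_vr; out[23] = en;
  }
  return true;
}

// [[Rcpp::export(name = ".mcl_core_rhs")]]
List mcl_core_rhs(NumericVector pvec, double t, NumericVector y) {
  if (pvec.size() != NPAR) stop("parameter vector has wrong length");
  std::vector<double> dy(NSTATE), out(NOUT);
  bool ok = rhs(t, REAL(y), REAL(pvec), dy.data(), out.data());
  return List::create(_["dy"] = NumericVector(dy.begin(), dy.end()),
                      _["aux"] = NumericVector(out.begin(), out.end()),
                      _["ok"] = ok);
}

// [[Rcpp::export(name = ".mcl_core_simulate")]]
List mcl_core_simulate(NumericVector pvec, NumericVector y0, double t0,
                       double duration, double dt, int method,
                       int record_every, double total_volume) {
  if (pvec.size() != NPAR) stop("parameter vector has wrong length");
  if (y0.size() != NSTATE) stop("state vector has wrong length");
  const double *p = REAL(pvec);
  long nsteps = (long)std::lround(duration / dt);
  long nrec = nsteps / record_every + 1;
  NumericMatrix traj(nrec, NOUT);

  double y[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE],
         ytmp[NSTATE], out[NOUT];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];
  if (p[E_ON] < 0.5) y[8] = 0.0;

  int status = 0;          // 0 ok, 1 flooded chamber, 2 non-finite, 3 unstable
  std::string bad = "";
  long irec = 0;

  // initial sample
  if (!rhs(t0, y, p, k1, out)) { status = 1; }
  for (int j = 0; j < NOUT; ++j) traj(0, j) = out[j];
  irec = 1;

  const double vol_cap = 10.0 * std::max(total_volume, 1.0);
  long step = 0;
  for (step = 0; step < nsteps && status == 0; ++step) {
    double t = t0 + step * dt;
    bool ok = true;
    if (method == 0) { // classical RK4
      ok = rhs(t, y, p, k1, NULL);
      if (ok) {
        for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + 0.5 * dt * k1[i];
        ok = rhs(t + 0.5 * dt, ytmp, p, k2, NULL);
      }
      if (ok) {
        for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + 0.5 * dt * k2[i];
        ok = rhs(t + 0.5 * dt, ytmp, p, k3, NULL);
      }
      if (ok) {
        for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + dt * k3[i];
        ok = rhs(t + dt, ytmp, p, k4, NULL);
      }
      if (ok)
        for (int i = 0; i < NSTATE; ++i)
          y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    } else {           // forward Euler (step-refinement cross-check)
      ok = rhs(t, y, p, k1, NULL);
      if (ok)
        for (int i = 0; i < NSTATE; ++i) y[i] += dt * k1[i];
    }
    if (!ok) { status = 1; bad = "windkessel chamber flooded"; break; }
    for (int i = 0; i < NSTATE; ++i) {
      if (!std::isfinite(y[i])) { status = 2; bad = "state component " + std::to_string(i + 1); break; }
      if (i < 8 && std::fabs(y[i]) > vol_cap) { status = 3; bad = "state component " + std::to_string(i + 1); break; }
    }
    if (status != 0) break;
    if ((step + 1) % record_every == 0) {
      if (!rhs(t + dt, y, p, k1, out)) { status = 1; bad = "windkessel chamber flooded"; break; }
      for (int j = 0; j < NOUT; ++j) traj(irec, j) = out[j];
      ++irec;
    }
  }

  if (irec < nrec) traj = traj(Range(0, std::max(irec - 1, (long)0)), Range(0, NOUT - 1));
  NumericVector yfin(y, y + NSTATE);
  return List::create(_["traj"] = traj, _["state"] = yfin,
                      _["status"] = status, _["message"] = bad,
                      _["steps_done"] = (double)step);
}
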