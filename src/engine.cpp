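// Closed-loop cardiovascular engine: time-varying elastance chambers with an
// actively contracting septum, pericardium, systemic + pulmonary networks,
// baroreflex, and an adaptive Cash-Karp RK4(5) integrator.
//
// All pressures mmHg, volumes ml, flows ml/s, time s.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// parameter containers

struct Wall {
  double E_ES, V_d, P_0, lambda, V_0;
};

struct Act {
  std::vector<double> A, B, C;
  double scale;
};

// vascular compartment order used throughout:
// 0 AOp  1 AOd  2 SA  3 SAd  4 SC  5 SVL  6 SV  7 VC
// 8 PAp  9 PAd 10 PA 11 PC  12 PV
static const int NVASC = 13;

// state vector layout:
// 0 V_LV  1 V_RV  2 V_LA  3 V_RA
// 4..16   vascular volumes (order above)
// 17 Q_AOp (AOp->AOd, inertial)  18 Q_AOd (AOd->SA)  19 Q_PAd (PAp->PAd)
// 20 msap_f  21 F_HRv  22 F_HRs  23 F_con  24 F_vaso
static const int NSTATE = 25;

struct Pars {
  Wall lvf, rvf, spt, la, ra;
  Act a_lvf, a_rvf, a_spt;
  double atr_B, atr_offset;            // atrial pulse width / offset
  double atr_amp_la, atr_amp_ra;       // per-atrium activation gain
  double peri_P0, peri_lam, peri_V0, peri_Vf;
  // resistances (mmHg s/ml)
  double R_M, R_AOp, R_AOd, R_SA, R_SAd, R_SC, R_SVL, R_SV, R_VC, R_RA,
         R_TC, R_PAp, R_PAd, R_PA, R_PC, R_PV, R_LA, R_PS, R_COR, R_CRB;
  double Cc[NVASC], Vun[NVASC];
  double L_AOp, L_AOd, L_PA;
  // neural maps
  double ab, bb;                       // F_b = clip(ab*MSAP + bb)
  double sl[4], ic[4];                 // limb = clip(ic + sl*F_b): HRv, HRs, con, vaso
  double h0, hs, hv;                   // HR = h0 + hs*F_HRs + hv*F_HRv
  double tau_s, tau_v, tau_msap;
  double k_alpha, Fcon_ref, Fvaso_ref, kR, kV;
  double hr_min, hr_max;
  int clamp_con, clamp_hr;
  double hr_ref_v, hr_ref_s;           // efferent values used when HR control clamped
};

static double getd(const List& L, const char* nm) {
  return as<double>(L[nm]);
}

static Act read_act(const List& a) {
  Act out;
  out.A = as<std::vector<double> >(a["A"]);
  out.B = as<std::vector<double> >(a["B"]);
  out.C = as<std::vector<double> >(a["C"]);
  out.scale = as<double>(a["scale"]);
  return out;
}

static Wall read_wall(const List& w) {
  Wall out;
  out.E_ES = getd(w, "E_ES"); out.V_d = getd(w, "V_d");
  out.P_0 = getd(w, "P_0"); out.lambda = getd(w, "lambda");
  out.V_0 = getd(w, "V_0");
  return out;
}

static Pars read_pars(const List& rp) {
  Pars P;
  List walls = rp["walls"];
  P.lvf = read_wall(walls["LVF"]); P.rvf = read_wall(walls["RVF"]);
  P.spt = read_wall(walls["SPT"]); P.la = read_wall(walls["LA"]);
  P.ra = read_wall(walls["RA"]);
  List acts = rp["activations"];
  P.a_lvf = read_act(acts["LVF"]); P.a_rvf = read_act(acts["RVF"]);
  P.a_spt = read_act(acts["SPT"]);
  List atr = rp["atrial"];
  P.atr_B = getd(atr, "B"); P.atr_offset = getd(atr, "offset");
  P.atr_amp_la = getd(atr, "amplitude_LA");
  P.atr_amp_ra = getd(atr, "amplitude_RA");
  List peri = rp["pericardium"];
  P.peri_P0 = getd(peri, "P_0"); P.peri_lam = getd(peri, "lambda");
  P.peri_V0 = getd(peri, "V_0"); P.peri_Vf = getd(peri, "V_fluid");
  NumericVector res = rp["resist"];
  P.R_M = res["R_M"]; P.R_AOp = res["R_AOp"]; P.R_AOd = res["R_AOd"];
  P.R_SA = res["R_SA"]; P.R_SAd = res["R_SAd"]; P.R_SC = res["R_SC"];
  P.R_SVL = res["R_SVL"]; P.R_SV = res["R_SV"]; P.R_VC = res["R_VC"];
  P.R_RA = res["R_RA"]; P.R_TC = res["R_TC"]; P.R_PAp = res["R_PAp"];
  P.R_PAd = res["R_PAd"]; P.R_PA = res["R_PA"]; P.R_PC = res["R_PC"];
  P.R_PV = res["R_PV"]; P.R_LA = res["R_LA"]; P.R_PS = res["R_PS"];
  P.R_COR = res["R_COR"]; P.R_CRB = res["R_CRB"];
  NumericVector cc = rp["compl"], vu = rp["vun"];
  for (int i = 0; i < NVASC; i++) { P.Cc[i] = cc[i]; P.Vun[i] = vu[i]; }
  NumericVector li = rp["inert"];
  P.L_AOp = li["L_AOp"]; P.L_AOd = li["L_AOd"]; P.L_PA = li["L_PA"];
  List ne = rp["neural"];
  P.ab = getd(ne, "ab"); P.bb = getd(ne, "bb");
  NumericVector sl = ne["slopes"], ic = ne["intercepts"];
  for (int i = 0; i < 4; i++) { P.sl[i] = sl[i]; P.ic[i] = ic[i]; }
  P.h0 = getd(ne, "h0"); P.hs = getd(ne, "hs"); P.hv = getd(ne, "hv");
  P.tau_s = getd(ne, "tau_symp"); P.tau_v = getd(ne, "tau_vagal");
  P.tau_msap = getd(ne, "tau_msap");
  P.k_alpha = getd(ne, "k_alpha");
  P.Fcon_ref = getd(ne, "F_con_ref"); P.Fvaso_ref = getd(ne, "F_vaso_ref");
  P.kR = getd(ne, "k_R"); P.kV = getd(ne, "k_V");
  P.hr_min = getd(ne, "hr_min"); P.hr_max = getd(ne, "hr_max");
  P.clamp_con = as<int>(rp["clamp_con"]);
  P.clamp_hr = as<int>(rp["clamp_hr"]);
  P.hr_ref_v = getd(ne, "hr_ref_v"); P.hr_ref_s = getd(ne, "hr_ref_s");
  return P;
}

// ---------------------------------------------------------------------------
// elemental laws

static inline double clip01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

static inline double act_val(double t, const Act& a) {
  double s = 0.0;
  for (size_t i = 0; i < a.A.size(); i++) {
    double u = (t - a.C[i]) / a.B[i];
    s += a.A[i] * std::exp(-0.5 * u * u);
  }
  return clip01(a.scale * s);
}

static inline double safe_expm1(double x) {
  if (x > 300.0) x = 300.0;
  return std::expm1(x);
}

static inline double wall_pes(double V, const Wall& w, double alpha) {
  return alpha * w.E_ES * (V - w.V_d);
}

static inline double wall_ped(double V, const Wall& w) {
  return w.P_0 * safe_expm1(w.lambda * (V - w.V_0));
}

static inline double wall_p(double e, double V, const Wall& w, double alpha) {
  return e * wall_pes(V, w, alpha) + (1.0 - e) * wall_ped(V, w);
}

// local dP/dV of the weighted wall law
static inline double wall_dpdv(double e, double V, const Wall& w, double alpha) {
  double ded = w.lambda * w.P_0 * std::exp(std::min(300.0, w.lambda * (V - w.V_0)));
  return e * alpha * w.E_ES + (1.0 - e) * ded;
}

// ---------------------------------------------------------------------------
// septal volume: fixed-point iteration (damping 0.5) with bisection fallback,
// then Newton polish so the result is independent of the starting value.

struct SeptalOut {
  double V_SPT, P_LVF, P_RVF, P_SPT;
  int iters;
  bool converged, fallback;
};

// inverse of the septal P-V law, weighted by activation (sign-mirrored
// diastolic branch: the law is odd about V = 0 since V_SPT,d = V_SPT,0 = 0)
static inline double spt_weighted_inverse(double Ps, double espt,
                                          const Wall& s, double alpha) {
  double Vsys = s.V_d + Ps / (alpha * s.E_ES);
  double Vdia;
  if (Ps >= 0.0)
    Vdia = s.V_0 + std::log1p(Ps / s.P_0) / s.lambda;
  else
    Vdia = s.V_0 - std::log1p(-Ps / s.P_0) / s.lambda;
  return espt * Vsys + (1.0 - espt) * Vdia;
}

static SeptalOut septal_solve(double VLV, double VRV, double elvf, double ervf,
                              double espt, const Pars& P, double alpha,
                              double Vinit, double damping, double tol,
                              int maxit) {
  SeptalOut out;
  out.fallback = false;
  double V = Vinit;
  int it = 0;
  bool conv = false;
  for (; it < maxit; it++) {
    double Pl = wall_p(elvf, VLV - V, P.lvf, alpha);
    double Pr = wall_p(ervf, VRV + V, P.rvf, alpha);
    double W = spt_weighted_inverse(Pl - Pr, espt, P.spt, alpha);
    double Vn = (1.0 - damping) * V + damping * W;
    double d = std::fabs(Vn - V);
    V = Vn;
    if (!std::isfinite(V) || std::fabs(V) > 1e4) break;
    if (d < tol) { conv = true; it++; break; }
  }
  out.iters = it;
  if (!conv) {
    // g(V) = V - W(V) is strictly increasing (W' < 0): bisect
    out.fallback = true;
    double lo = -60.0, hi = 80.0;
    for (int k = 0; k < 8; k++) {
      double Pl = wall_p(elvf, VLV - lo, P.lvf, alpha);
      double Pr = wall_p(ervf, VRV + lo, P.rvf, alpha);
      if (lo - spt_weighted_inverse(Pl - Pr, espt, P.spt, alpha) < 0.0) break;
      lo -= 60.0;
    }
    for (int k = 0; k < 8; k++) {
      double Pl = wall_p(elvf, VLV - hi, P.lvf, alpha);
      double Pr = wall_p(ervf, VRV + hi, P.rvf, alpha);
      if (hi - spt_weighted_inverse(Pl - Pr, espt, P.spt, alpha) > 0.0) break;
      hi += 80.0;
    }
    for (int k = 0; k < 80; k++) {
      double mid = 0.5 * (lo + hi);
      double Pl = wall_p(elvf, VLV - mid, P.lvf, alpha);
      double Pr = wall_p(ervf, VRV + mid, P.rvf, alpha);
      double g = mid - spt_weighted_inverse(Pl - Pr, espt, P.spt, alpha);
      if (g > 0.0) hi = mid; else lo = mid;
      if (hi - lo < 1e-10) break;
    }
    V = 0.5 * (lo + hi);
  }
  // Newton polish on g(V) = V - W(V): g' = 1 + inv_slope * (E_lvf + E_rvf) > 1
  for (int k = 0; k < 6; k++) {
    double Pl = wall_p(elvf, VLV - V, P.lvf, alpha);
    double Pr = wall_p(ervf, VRV + V, P.rvf, alpha);
    double Ps = Pl - Pr;
    double g = V - spt_weighted_inverse(Ps, espt, P.spt, alpha);
    double inv_slope = espt / (alpha * P.spt.E_ES) +
      (1.0 - espt) / (P.spt.lambda * (P.spt.P_0 + std::fabs(Ps)));
    double El = wall_dpdv(elvf, VLV - V, P.lvf, alpha);
    double Er = wall_dpdv(ervf, VRV + V, P.rvf, alpha);
    double gp = 1.0 + inv_slope * (El + Er);
    double step = g / gp;
    V -= step;
    if (std::fabs(step) < 1e-13) break;
  }
  out.V_SPT = V;
  out.P_LVF = wall_p(elvf, VLV - V, P.lvf, alpha);
  out.P_RVF = wall_p(ervf, VRV + V, P.rvf, alpha);
  out.P_SPT = out.P_LVF - out.P_RVF;
  out.converged = true;
  return out;
}

// [[Rcpp::export]]
List cpp_septal_solve(double V_LV, double V_RV, double e_LVF, double e_RVF,
                      double e_SPT, List params, double alpha,
                      double V_SPT_init, double damping, double tol,
                      int maxit) {
  Pars P = read_pars(params);
  SeptalOut s = septal_solve(V_LV, V_RV, e_LVF, e_RVF, e_SPT, P, alpha,
                             V_SPT_init, damping, tol, maxit);
  return List::create(_["V_SPT"] = s.V_SPT, _["P_LVF"] = s.P_LVF,
                      _["P_RVF"] = s.P_RVF, _["P_SPT"] = s.P_SPT,
                      _["iterations"] = s.iters,
                      _["fallback"] = s.fallback);
}

// ---------------------------------------------------------------------------
// full right-hand side

static const int NAUX = 48;

static inline double pleural(double t, int mode) {
  if (mode == 0) return -5.0;
  return -4.0 - 2.0 * std::cos(2.0 * M_PI * t / 7.0);
}

// aux layout (names mirrored in R):
// 0 P_LV 1 P_RV 2 P_LA 3 P_RA 4 P_PERI 5 P_SPT 6 V_SPT
// 7..19  vascular pressures (order above)
// 20 P_PL
// 21 Q_M 22 Q_AO 23 Q_TC 24 Q_PAV 25 Q_RA 26 Q_LA 27 Q_COR 28 Q_CRB
// 29 Q_SA 30 Q_SC 31 Q_SVL 32 Q_SV 33 Q_VC 34 Q_PAr 35 Q_PC 36 Q_PV 37 Q_PS
// 38 e_LVF 39 e_RVF 40 e_SPT 41 e_A 42 alpha 43 F_b 44 spt_iters
// 45 HR_target 46 phase 47 period
static void rhs(double t, double phase, double period, const double* y,
                double* dy, double* aux, const Pars& P, int pleural_mode,
                double& vspt_cache) {
  const double P_PL = pleural(t, pleural_mode);

  const double e_lvf = act_val(phase, P.a_lvf);
  const double e_rvf = act_val(phase, P.a_rvf);
  const double e_spt = act_val(phase, P.a_spt);
  // atrial pulse peaks `atr_offset` s before cycle end; the wrap term keeps
  // atrial relaxation continuous across the beat boundary (x-descent)
  double ua = (phase - (period - P.atr_offset)) / P.atr_B;
  double uw = (phase + P.atr_offset) / P.atr_B;
  const double e_a = std::exp(-ua * ua) + std::exp(-uw * uw);
  const double e_la = P.atr_amp_la * e_a, e_ra = P.atr_amp_ra * e_a;

  const double F_con = P.clamp_con ? P.Fcon_ref : y[23];
  double alpha = 1.0 + P.k_alpha * (F_con - P.Fcon_ref);
  if (alpha < 1.0) alpha = 1.0;

  SeptalOut s = septal_solve(y[0], y[1], e_lvf, e_rvf, e_spt, P, alpha,
                             vspt_cache, 0.5, 1e-6, 100);
  vspt_cache = s.V_SPT;

  const double Vheart = y[0] + y[1] + y[2] + y[3] + P.peri_Vf;
  const double P_PERI =
      P.peri_P0 * safe_expm1(P.peri_lam * (Vheart - P.peri_V0)) + P_PL;

  const double P_LV = s.P_LVF + P_PERI;
  const double P_RV = s.P_RVF + P_PERI;
  const double P_LA = wall_p(e_la, y[2], P.la, 1.0) + P_PERI;
  const double P_RA = wall_p(e_ra, y[3], P.ra, 1.0) + P_PERI;

  // vasomotor tone: arteriolar resistance up, venous unstressed volume down
  const double fv = y[24];
  double R_SAd_eff = P.R_SAd * (1.0 + P.kR * (fv - P.Fvaso_ref));
  if (R_SAd_eff < 0.05 * P.R_SAd) R_SAd_eff = 0.05 * P.R_SAd;
  const double Vun_SV_eff = P.Vun[6] - P.kV * (fv - P.Fvaso_ref);

  double Pv[NVASC];
  for (int i = 0; i < NVASC; i++) {
    double vun = (i == 6) ? Vun_SV_eff : P.Vun[i];
    // thoracic: AOp(0), VC(7), PAp(8), PAd(9), PA(10), PC(11), PV(12)
    double pext = (i == 0 || i >= 7) ? P_PL : 0.0;
    Pv[i] = (y[4 + i] - vun) / P.Cc[i] + pext;
  }

  const double Q_M = std::max(0.0, (P_LA - P_LV) / P.R_M);
  const double Q_AO = std::max(0.0, (P_LV - Pv[0]) / P.R_AOp);
  const double Q_TC = std::max(0.0, (P_RA - P_RV) / P.R_TC);
  const double Q_PAV = std::max(0.0, (P_RV - Pv[8]) / P.R_PAp);

  const double Q_AOp = y[17], Q_AOd = y[18], Q_PAd = y[19];
  const double Q_COR = (Pv[0] - Pv[7]) / P.R_COR;
  const double Q_CRB = (Pv[0] - Pv[7]) / P.R_CRB;
  const double Q_SA = (Pv[2] - Pv[3]) / R_SAd_eff;
  const double Q_SC = (Pv[3] - Pv[4]) / P.R_SC;
  const double Q_SVL = (Pv[4] - Pv[5]) / P.R_SVL;
  const double Q_SV = (Pv[5] - Pv[6]) / P.R_SV;
  const double Q_VC = (Pv[6] - Pv[7]) / P.R_VC;
  const double Q_RA = (Pv[7] - P_RA) / P.R_RA;
  const double Q_PAr = (Pv[9] - Pv[10]) / P.R_PA;
  const double Q_PC = (Pv[10] - Pv[11]) / P.R_PC;
  const double Q_PV = (Pv[11] - Pv[12]) / P.R_PV;
  const double Q_PS = (Pv[10] - Pv[12]) / P.R_PS;
  const double Q_LA = (Pv[12] - P_LA) / P.R_LA;

  dy[0] = Q_M - Q_AO;              // V_LV
  dy[1] = Q_TC - Q_PAV;            // V_RV
  dy[2] = Q_LA - Q_M;              // V_LA
  dy[3] = Q_RA - Q_TC;             // V_RA
  dy[4] = Q_AO - Q_AOp - Q_COR - Q_CRB;   // AOp
  dy[5] = Q_AOp - Q_AOd;           // AOd
  dy[6] = Q_AOd - Q_SA;            // SA
  dy[7] = Q_SA - Q_SC;             // SAd
  dy[8] = Q_SC - Q_SVL;            // SC
  dy[9] = Q_SVL - Q_SV;            // SVL
  dy[10] = Q_SV - Q_VC;            // SV
  dy[11] = Q_VC + Q_COR + Q_CRB - Q_RA;   // VC
  dy[12] = Q_PAV - Q_PAd;          // PAp
  dy[13] = Q_PAd - Q_PAr;          // PAd
  dy[14] = Q_PAr - Q_PC - Q_PS;    // PA
  dy[15] = Q_PC - Q_PV;            // PC
  dy[16] = Q_PV + Q_PS - Q_LA;     // PV

  dy[17] = (Pv[0] - Pv[1] - P.R_AOd * Q_AOp) / P.L_AOp;
  dy[18] = (Pv[1] - Pv[2] - P.R_SA * Q_AOd) / P.L_AOd;
  dy[19] = (Pv[8] - Pv[9] - P.R_PAd * Q_PAd) / P.L_PA;

  // neural limbs
  dy[20] = (Pv[0] - y[20]) / P.tau_msap;
  const double F_b = clip01(P.ab * y[20] + P.bb);
  const double T_HRv = clip01(P.ic[0] + P.sl[0] * F_b);
  const double T_HRs = clip01(P.ic[1] + P.sl[1] * F_b);
  const double T_con = clip01(P.ic[2] + P.sl[2] * F_b);
  const double T_vaso = clip01(P.ic[3] + P.sl[3] * F_b);
  dy[21] = P.clamp_hr ? 0.0 : (T_HRv - y[21]) / P.tau_v;
  dy[22] = P.clamp_hr ? 0.0 : (T_HRs - y[22]) / P.tau_s;
  dy[23] = P.clamp_con ? 0.0 : (T_con - y[23]) / P.tau_s;
  dy[24] = (T_vaso - y[24]) / P.tau_s;

  if (aux) {
    aux[0] = P_LV; aux[1] = P_RV; aux[2] = P_LA; aux[3] = P_RA;
    aux[4] = P_PERI; aux[5] = s.P_SPT; aux[6] = s.V_SPT;
    for (int i = 0; i < NVASC; i++) aux[7 + i] = Pv[i];
    aux[20] = P_PL;
    aux[21] = Q_M; aux[22] = Q_AO; aux[23] = Q_TC; aux[24] = Q_PAV;
    aux[25] = Q_RA; aux[26] = Q_LA; aux[27] = Q_COR; aux[28] = Q_CRB;
    aux[29] = Q_SA; aux[30] = Q_SC; aux[31] = Q_SVL; aux[32] = Q_SV;
    aux[33] = Q_VC; aux[34] = Q_PAr; aux[35] = Q_PC; aux[36] = Q_PV;
    aux[37] = Q_PS;
    aux[38] = e_lvf; aux[39] = e_rvf; aux[40] = e_spt; aux[41] = e_a;
    aux[42] = alpha; aux[43] = F_b; aux[44] = (double)s.iters;
    double fhv = P.clamp_hr ? P.hr_ref_v : y[21];
    double fhs = P.clamp_hr ? P.hr_ref_s : y[22];
    double hr = P.h0 + P.hs * fhs + P.hv * fhv;
    if (hr < P.hr_min) hr = P.hr_min;
    if (hr > P.hr_max) hr = P.hr_max;
    aux[45] = hr;
    aux[46] = phase; aux[47] = period;
  }
}

// [[Rcpp::export]]
List cpp_rhs(List params, NumericVector state, double phase, double period,
             double t, int pleural_mode, double vspt_init) {
  Pars P = read_pars(params);
  if (state.size() != NSTATE) stop("state must have length %d", NSTATE);
  std::vector<double> dy(NSTATE), aux(NAUX);
  double cache = vspt_init;
  rhs(t, phase, period, REAL(state), dy.data(), aux.data(), P, pleural_mode,
      cache);
  return List::create(_["deriv"] = NumericVector(dy.begin(), dy.end()),
                      _["aux"] = NumericVector(aux.begin(), aux.end()));
}

// ---------------------------------------------------------------------------
// Cash-Karp embedded RK4(5) tableau

static const double ck_c[6] = {0.0, 1.0/5, 3.0/10, 3.0/5, 1.0, 7.0/8};
static const double ck_a[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0/5, 0, 0, 0, 0},
  {3.0/40, 9.0/40, 0, 0, 0},
  {3.0/10, -9.0/10, 6.0/5, 0, 0},
  {-11.0/54, 5.0/2, -70.0/27, 35.0/27, 0},
  {1631.0/55296, 175.0/512, 575.0/13824, 44275.0/110592, 253.0/4096}};
static const double ck_b5[6] = {37.0/378, 0, 250.0/621, 125.0/594, 0,
                                512.0/1771};
static const double ck_b4[6] = {2825.0/27648, 0, 18575.0/48384,
                                13525.0/55296, 277.0/14336, 1.0/4};

// ---------------------------------------------------------------------------
// full simulation

// [[Rcpp::export]]
List cpp_simulate(List params, NumericVector init, double phase0,
                  double period0, double duration, double dt_report,
                  int pleural_mode, double rtol, double atol) {
  Pars P = read_pars(params);
  if (init.size() != NSTATE) stop("init must have length %d", NSTATE);

  const int nrec = (int)std::floor(duration / dt_report + 0.5) + 1;
  const int ncol = 1 + NSTATE + NAUX;
  NumericMatrix traj(nrec, ncol);

  std::vector<double> y(REAL(init), REAL(init) + NSTATE);
  std::vector<double> k[6];
  for (int i = 0; i < 6; i++) k[i].resize(NSTATE);
  std::vector<double> ytmp(NSTATE), y5(NSTATE), y4(NSTATE), aux(NAUX);

  double vspt_cache = 0.0;
  double t = 0.0;
  double beat_start = -phase0;
  double period = period0;
  double beat_end = beat_start + period;
  double h = 1e-4;
  const double hmax = 2.0 * dt_report, hmin = 1e-10;

  std::vector<double> beat_onsets, beat_periods;
  beat_onsets.push_back(beat_start);
  beat_periods.push_back(period);

  long nstep = 0, nreject = 0;
  double spt_iter_sum = 0.0;
  long spt_fallbacks = 0, naccept = 0;

  // record initial point
  int irec = 0;
  {
    std::vector<double> dy(NSTATE);
    rhs(t, t - beat_start, period, y.data(), dy.data(), aux.data(), P,
        pleural_mode, vspt_cache);
    traj(0, 0) = t;
    for (int j = 0; j < NSTATE; j++) traj(0, 1 + j) = y[j];
    for (int j = 0; j < NAUX; j++) traj(0, 1 + NSTATE + j) = aux[j];
    irec = 1;
  }
  double next_grid = dt_report;

  while (t < duration - 1e-12 && irec < nrec) {
    double t_stop = std::min(next_grid, beat_end);
    if (t_stop > duration) t_stop = duration;
    double h_use = std::min(h, t_stop - t);
    if (h_use < hmin) h_use = hmin;

    // stages
    rhs(t, t - beat_start, period, y.data(), k[0].data(), NULL, P,
        pleural_mode, vspt_cache);
    bool bad = false;
    for (int s = 1; s < 6; s++) {
      for (int j = 0; j < NSTATE; j++) {
        double acc = 0.0;
        for (int q = 0; q < s; q++) acc += ck_a[s][q] * k[q][j];
        ytmp[j] = y[j] + h_use * acc;
      }
      double tt = t + ck_c[s] * h_use;
      rhs(tt, tt - beat_start, period, ytmp.data(), k[s].data(), NULL, P,
          pleural_mode, vspt_cache);
    }
    double errnorm = 0.0;
    for (int j = 0; j < NSTATE; j++) {
      double s5 = 0.0, s4 = 0.0;
      for (int q = 0; q < 6; q++) {
        s5 += ck_b5[q] * k[q][j];
        s4 += ck_b4[q] * k[q][j];
      }
      y5[j] = y[j] + h_use * s5;
      y4[j] = y[j] + h_use * s4;
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(y5[j]));
      double e = (y5[j] - y4[j]) / sc;
      errnorm += e * e;
      if (!std::isfinite(y5[j])) bad = true;
    }
    errnorm = std::sqrt(errnorm / NSTATE);
    // volumes must stay non-negative
    for (int j = 0; j < 17; j++) if (y5[j] < 0.0) bad = true;

    nstep++;
    if (!bad && errnorm <= 1.0) {
      t += h_use;
      y = y5;
      naccept++;
      // track septal effort at the accepted state
      SeptalOut s = septal_solve(
          y[0], y[1], act_val(t - beat_start, P.a_lvf),
          act_val(t - beat_start, P.a_rvf), act_val(t - beat_start, P.a_spt),
          P, 1.0, vspt_cache, 0.5, 1e-6, 100);
      vspt_cache = s.V_SPT;
      spt_iter_sum += s.iters;
      if (s.fallback) spt_fallbacks++;

      if (std::fabs(t - next_grid) < 1e-9 && irec < nrec) {
        std::vector<double> dy(NSTATE);
        rhs(t, t - beat_start, period, y.data(), dy.data(), aux.data(), P,
            pleural_mode, vspt_cache);
        traj(irec, 0) = t;
        for (int j = 0; j < NSTATE; j++) traj(irec, 1 + j) = y[j];
        for (int j = 0; j < NAUX; j++) traj(irec, 1 + NSTATE + j) = aux[j];
        irec++;
        next_grid += dt_report;
      }
      if (std::fabs(t - beat_end) < 1e-9) {
        // sample the next beat period from current efferent activity
        double fhv = P.clamp_hr ? P.hr_ref_v : y[21];
        double fhs = P.clamp_hr ? P.hr_ref_s : y[22];
        double hr = P.h0 + P.hs * fhs + P.hv * fhv;
        if (hr < P.hr_min) hr = P.hr_min;
        if (hr > P.hr_max) hr = P.hr_max;
        period = 60.0 / hr;
        beat_start = t;
        beat_end = t + period;
        beat_onsets.push_back(beat_start);
        beat_periods.push_back(period);
      }
      double fac = errnorm > 1e-12 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h = std::min(hmax, h_use * fac);
    } else {
      nreject++;
      double fac = (bad || errnorm <= 0.0) ? 0.25
                   : std::max(0.1, 0.9 * std::pow(errnorm, -0.25));
      h = h_use * fac;
      if (h < hmin)
        stop("step size underflow at t = %g (err = %g)", t, errnorm);
    }
  }

  return List::create(
      _["traj"] = traj, _["n_rec"] = irec,
      _["beat_onsets"] = NumericVector(beat_onsets.begin(), beat_onsets.end()),
      _["beat_periods"] =
          NumericVector(beat_periods.begin(), beat_periods.end()),
      _["final_state"] = NumericVector(y.begin(), y.end()),
      _["final_phase"] = t - beat_start, _["final_period"] = period,
      _["n_steps"] = (double)nstep, _["n_reject"] = (double)nreject,
      _["spt_iter_mean"] = naccept ? spt_iter_sum / naccept : 0.0,
      _["spt_fallbacks"] = (double)spt_fallbacks);
}

// ---------------------------------------------------------------------------
// generic Cash-Karp integrator over an R right-hand side (for solver
// verification against closed-form problems)

// [[Rcpp::export]]
List cpp_ck_integrate(Function f, NumericVector y0, double t0, double t1,
                      double rtol, double atol, double hmax) {
  const int n = y0.size();
  std::vector<double> y(REAL(y0), REAL(y0) + n);
  std::vector<std::vector<double> > k(6, std::vector<double>(n));
  std::vector<double> ytmp(n), y5(n), y4(n);
  std::vector<double> ts;
  std::vector<std::vector<double> > ys;
  ts.push_back(t0);
  ys.push_back(y);
  double t = t0, h = std::min(hmax, (t1 - t0) / 10.0);
  const double hmin = 1e-12;
  long nstep = 0;
  while (t < t1 - 1e-12) {
    double h_use = std::min(h, t1 - t);
    for (int s = 0; s < 6; s++) {
      for (int j = 0; j < n; j++) {
        double acc = 0.0;
        for (int q = 0; q < s; q++) acc += ck_a[s][q] * k[q][j];
        ytmp[j] = y[j] + h_use * acc;
      }
      NumericVector kv =
          f(t + ck_c[s] * h_use, NumericVector(ytmp.begin(), ytmp.end()));
      for (int j = 0; j < n; j++) k[s][j] = kv[j];
    }
    double errnorm = 0.0;
    for (int j = 0; j < n; j++) {
      double s5 = 0.0, s4 = 0.0;
      for (int q = 0; q < 6; q++) {
        s5 += ck_b5[q] * k[q][j];
        s4 += ck_b4[q] * k[q][j];
      }
      y5[j] = y[j] + h_use * s5;
      y4[j] = y[j] + h_use * s4;
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(y5[j]));
      double e = (y5[j] - y4[j]) / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / n);
    if (errnorm <= 1.0) {
      t += h_use;
      y = y5;
      ts.push_back(t);
      ys.push_back(y);
      double fac = errnorm > 1e-12 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h = std::min(hmax, h_use * fac);
    } else {
      h = h_use * std::max(0.1, 0.9 * std::pow(errnorm, -0.25));
      if (h < hmin) stop("step size underflow in cpp_ck_integrate");
    }
    if (++nstep > 2000000) stop("too many steps in cpp_ck_integrate");
  }
  NumericMatrix Y(ts.size(), n);
  for (size_t i = 0; i < ts.size(); i++)
    for (int j = 0; j < n; j++) Y(i, j) = ys[i][j];
  return List::create(_["t"] = NumericVector(ts.begin(), ts.end()),
                      _["y"] = Y, _["n_steps"] = (double)nstep);
}
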