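// Courtemanche-Ramirez-Nattel (1998) human atrial myocyte model.
// State layout (21 doubles per node):
//   0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
//   10 d, 11 f, 12 fca, 13 u, 14 v, 15 w,
//   16 Nai, 17 Ki, 18 Cai, 19 Caup, 20 Carel
// Remodeling scales: 0 Ito, 1 IKur, 2 ICaL, 3 IK1 (multipliers on gmax).
#ifndef AFSIM_CRN_MODEL_H
#define AFSIM_CRN_MODEL_H

#include <vector>
#include <cmath>
#include <stdexcept>
#include <string>

namespace crn {

constexpr int NSTATE = 21;

// physical constants
constexpr double Rgas = 8.3143, Temp = 310.0, Fdy = 96.4867;
constexpr double FRT = Fdy / (Rgas * Temp);
constexpr double Cm = 100.0;                 // pF
constexpr double Vi = 13668.0, Vup = 1109.52, Vrel = 96.48;  // um^3
constexpr double Ko = 5.4, Nao = 140.0, Cao = 1.8;           // mM
constexpr double gna = 7.8, gk1 = 0.09, gto = 0.1652;
constexpr double gkr = 0.029411765, gks = 0.12941176, gcal = 0.12375;
constexpr double gbca = 0.001131, gbna = 0.0006744375;
constexpr double inakmax = 0.59933874, kmnai = 10.0, kmko = 1.5;
constexpr double inacamax = 1600.0, kmna = 87.5, kmca = 1.38;
constexpr double ksat = 0.1, gam = 0.35;
constexpr double ipcamax = 0.275;
constexpr double krel = 30.0;
constexpr double kup = 0.00092, iupmax = 0.005, caupmax = 15.0;
constexpr double tautr = 180.0;
constexpr double cmdnmax = 0.05, trpnmax = 0.07, csqnmax = 10.0;
constexpr double kmcmdn = 0.00238, kmtrpn = 0.0005, kmcsqn = 0.8;
constexpr double KQ10 = 3.0;

// published initial conditions (quiescent cell)
inline void default_state(double* y) {
  const double y0[NSTATE] = {
    -81.18, 2.908e-3, 9.649e-1, 9.775e-1, 3.043e-2, 9.992e-1,
    4.966e-3, 9.986e-1, 3.296e-5, 1.869e-2, 1.367e-4, 9.996e-1,
    7.755e-1, 0.0, 1.0, 9.992e-1, 1.117e1, 1.39e2, 1.013e-4,
    1.488, 1.488 };
  for (int k = 0; k < NSTATE; ++k) y[k] = y0[k];
}

inline double sq(double x) { return x * x; }
inline double cube(double x) { return x * x * x; }

// safe x/(1-exp(-x/s)) style helpers evaluated with limits at singular points
inline double guard_div(double num, double den, double lim) {
  return std::fabs(den) < 1e-10 ? lim : num / den;
}

// V-dependent gate kinetics: fills inf[12] and tau[12] in gate order
// m h j oa oi ua ui xr xs d f w
inline void gate_rates(double V, double* inf, double* tau) {
  // INa gates (Luo-Rudy kinetics as used by CRN)
  double am = std::fabs(V + 47.13) < 1e-10 ? 3.2
    : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
      (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  inf[0] = am / (am + bm); tau[0] = 1.0 / (am + bm);
  inf[1] = ah / (ah + bh); tau[1] = 1.0 / (ah + bh);
  inf[2] = aj / (aj + bj); tau[2] = 1.0 / (aj + bj);
  // Ito
  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  tau[3] = 1.0 / ((aoa + boa) * KQ10);
  inf[3] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  tau[4] = 1.0 / ((aoi + boi) * KQ10);
  inf[4] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  // IKur (activation kinetics shared with oa)
  tau[5] = 1.0 / ((aoa + boa) * KQ10);
  inf[5] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  tau[6] = 1.0 / ((aui + bui) * KQ10);
  inf[6] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  // IKr
  double axr = std::fabs(V + 14.1) < 1e-10 ? 0.0015
    : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  double bxr = std::fabs(V - 3.3328) < 1e-10 ? 3.7836118e-4
    : 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  tau[7] = 1.0 / (axr + bxr);
  inf[7] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  // IKs
  double axs = std::fabs(V - 19.9) < 1e-10 ? 0.00068
    : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  double bxs = std::fabs(V - 19.9) < 1e-10 ? 0.000315
    : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  tau[8] = 0.5 / (axs + bxs);
  inf[8] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  // ICaL
  double e10 = std::exp(-(V + 10.0) / 6.24);
  tau[9] = std::fabs(V + 10.0) < 1e-10 ? 4.579 / (1.0 + e10)
    : (1.0 - e10) / (0.035 * (V + 10.0) * (1.0 + e10));
  inf[9] = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  tau[10] = 9.0 / (0.0197 * std::exp(-sq(0.0337) * sq(V + 10.0)) + 0.02);
  inf[10] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  // Irel w gate
  double e79 = std::exp(-(V - 7.9) / 5.0);
  tau[11] = std::fabs(V - 7.9) < 1e-10 ? 6.0 * 0.2 / 1.3
    : 6.0 * (1.0 - e79) / ((1.0 + 0.3 * e79) * (V - 7.9));
  inf[11] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
}

// All membrane + SR currents at a state, in pA/pF (membrane) and mM/ms (SR
// fluxes).  Fills cur[14]:
// 0 INa 1 IK1 2 Ito 3 IKur 4 IKr 5 IKs 6 ICaL 7 IpCa 8 INaK 9 INaCa
// 10 IbNa 11 IbCa 12 Irel(mM/ms) 13 Fn
inline void currents(const double* y, const double* s, double* cur) {
  double V = y[0];
  double ena = std::log(Nao / y[16]) / FRT;
  double ek  = std::log(Ko / y[17]) / FRT;
  double eca = std::log(Cao / y[18]) / (2.0 * FRT);
  cur[0] = gna * cube(y[1]) * y[2] * y[3] * (V - ena);
  cur[1] = s[3] * gk1 * (V - ek) / (1.0 + std::exp(0.07 * (V + 80.0)));
  cur[2] = s[0] * gto * cube(y[4]) * y[5] * (V - ek);
  double gkur = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
  cur[3] = s[1] * gkur * cube(y[6]) * y[7] * (V - ek);
  cur[4] = gkr * y[8] * (V - ek) / (1.0 + std::exp((V + 15.0) / 22.4));
  cur[5] = gks * sq(y[9]) * (V - ek);
  cur[6] = s[2] * gcal * y[10] * y[11] * y[12] * (V - 65.0);
  cur[7] = ipcamax * y[18] / (0.0005 + y[18]);
  double sig = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * FRT * V) +
                       0.0365 * sig * std::exp(-FRT * V));
  cur[8] = inakmax * fnak / (1.0 + std::pow(kmnai / y[16], 1.5)) *
    (Ko / (Ko + kmko));
  double ega = std::exp(gam * FRT * V), egb = std::exp((gam - 1.0) * FRT * V);
  cur[9] = inacamax * (ega * cube(y[16]) * Cao - egb * cube(Nao) * y[18]) /
    ((cube(kmna) + cube(Nao)) * (kmca + Cao) * (1.0 + ksat * egb));
  cur[10] = gbna * (V - ena);
  cur[11] = gbca * (V - eca);
  cur[12] = krel * sq(y[13]) * y[14] * y[15] * (y[20] - y[18]);
  cur[13] = 1e-12 * Vrel * cur[12] -
    (5e-13 / Fdy) * (0.5 * cur[6] * Cm - 0.2 * cur[9] * Cm);
  return;
}

// ---- lookup tables for the tissue-scale integrator -------------------------
// Three time-step banks: dt, dt/2, dt/10 (Rush-Larsen gate factors are
// precomputed per bank).  V grid [-120, 80] mV at 0.05 mV.
struct Tables {
  static constexpr double vmin = -120.0, vmax = 80.0, dv = 0.05;
  int n = 0;
  double dts[3];
  // per grid point: 12 gate infs, then 3 banks x 12 gate RL factors
  std::vector<double> ginf;            // 12*n
  std::vector<double> gef[3];          // 12*n each
  // V-dependent current coefficients: 0 ik1f (gk1 rectifier), 1 gkur,
  // 2 ikrf, 3 fnak, 4 ega, 5 egb
  std::vector<double> coef;            // 6*n
  double efca[3], eu[3];               // constant-tau RL factors (fca, u)

  void build(double dt_max) {
    dts[0] = dt_max; dts[1] = dt_max / 2.0; dts[2] = dt_max / 10.0;
    n = (int)std::lround((vmax - vmin) / dv) + 1;
    ginf.assign(12 * n, 0.0);
    for (int b = 0; b < 3; ++b) gef[b].assign(12 * n, 0.0);
    coef.assign(6 * n, 0.0);
    double inf[12], tau[12];
    double sig = (std::exp(Nao / 67.3) - 1.0) / 7.0;
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      gate_rates(V, inf, tau);
      for (int g = 0; g < 12; ++g) {
        ginf[12 * i + g] = inf[g];
        for (int b = 0; b < 3; ++b)
          gef[b][12 * i + g] = std::exp(-dts[b] / tau[g]);
      }
      coef[6 * i + 0] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
      coef[6 * i + 1] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
      coef[6 * i + 2] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
      coef[6 * i + 3] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * FRT * V) +
                               0.0365 * sig * std::exp(-FRT * V));
      coef[6 * i + 4] = std::exp(gam * FRT * V);
      coef[6 * i + 5] = std::exp((gam - 1.0) * FRT * V);
    }
    for (int b = 0; b < 3; ++b) {
      efca[b] = std::exp(-dts[b] / 2.0);
      eu[b] = std::exp(-dts[b] / 8.0);
    }
  }
};

// Advance the reaction part of one node by n_sub substeps of tables.dts[bank].
// aux = {ena, ek, eca, inak_conc_factor} cached Nernst-level quantities.
// istim: depolarizing stimulus in pA/pF (positive depolarizes).
// Returns the new V.  Throws std::runtime_error on NaN/overflow.
inline double step_node(double* y, const Tables& T, int bank, int n_sub,
                        const double* s, double istim, const double* aux) {
  const double dt = T.dts[bank];
  for (int it = 0; it < n_sub; ++it) {
    double V = y[0];
    if (!(V > -250.0 && V < 250.0))
      throw std::runtime_error("membrane potential out of range");
    double x = (V - T.vmin) / T.dv;
    if (x < 0.0) x = 0.0;
    if (x > T.n - 1.001) x = T.n - 1.001;
    int i0 = (int)x;
    double fr = x - i0;
    const double* inf0 = &T.ginf[12 * i0];
    const double* ef0 = &T.gef[bank][12 * i0];
    double inf[12], ef[12];
    for (int g = 0; g < 12; ++g) {
      inf[g] = inf0[g] + fr * (inf0[g + 12] - inf0[g]);
      ef[g] = ef0[g] + fr * (ef0[g + 12] - ef0[g]);
    }
    const double* c0 = &T.coef[6 * i0];
    double co[6];
    for (int k = 0; k < 6; ++k) co[k] = c0[k] + fr * (c0[k + 6] - c0[k]);

    // currents (pA/pF)
    double ina = gna * cube(y[1]) * y[2] * y[3] * (V - aux[0]);
    double ik1 = s[3] * gk1 * (V - aux[1]) * co[0];
    double ito = s[0] * gto * cube(y[4]) * y[5] * (V - aux[1]);
    double ikur = s[1] * co[1] * cube(y[6]) * y[7] * (V - aux[1]);
    double ikr = gkr * y[8] * (V - aux[1]) * co[2];
    double iks = gks * sq(y[9]) * (V - aux[1]);
    double ical = s[2] * gcal * y[10] * y[11] * y[12] * (V - 65.0);
    double ipca = ipcamax * y[18] / (0.0005 + y[18]);
    double inak = inakmax * co[3] * aux[3];
    double inaca = inacamax *
      (co[4] * cube(y[16]) * Cao - co[5] * cube(Nao) * y[18]) /
      ((cube(kmna) + cube(Nao)) * (kmca + Cao) * (1.0 + ksat * co[5]));
    double ibna = gbna * (V - aux[0]);
    double ibca = gbca * (V - aux[2]);
    double irel = krel * sq(y[13]) * y[14] * y[15] * (y[20] - y[18]);
    double itr = (y[19] - y[20]) / tautr;
    double iup = iupmax / (1.0 + kup / y[18]);
    double iupleak = iupmax * y[19] / caupmax;

    // gates: Rush-Larsen with tabulated factors
    for (int g = 0; g < 12; ++g) {
      static const int idx[12] = {1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 15};
      double& gv = y[idx[g]];
      gv = inf[g] + (gv - inf[g]) * ef[g];
    }
    // Ca-dependent gates
    double fcainf = 1.0 / (1.0 + y[18] / 0.00035);
    y[12] = fcainf + (y[12] - fcainf) * T.efca[bank];
    double fn = 1e-12 * Vrel * irel -
      (5e-13 / Fdy) * (0.5 * ical * Cm - 0.2 * inaca * Cm);
    double arg = (fn - 3.4175e-13) / 13.67e-16;
    double sg = arg > 35.0 ? 1.0 : (arg < -35.0 ? 0.0
                 : 1.0 / (1.0 + std::exp(-arg)));
    y[13] = sg + (y[13] - sg) * T.eu[bank];
    double tauv = 1.91 + 2.09 * sg;
    double arg2 = (fn - 6.835e-14) / 13.67e-16;
    double vinf = arg2 > 35.0 ? 0.0 : (arg2 < -35.0 ? 1.0
                   : 1.0 - 1.0 / (1.0 + std::exp(-arg2)));
    y[14] += dt * (vinf - y[14]) / tauv;

    // concentrations (forward Euler; currents to pA via Cm)
    y[16] += dt * (-3.0 * inak - 3.0 * inaca - ibna - ina) * Cm / (Fdy * Vi);
    y[17] += dt * (2.0 * inak - ik1 - ito - ikur - ikr - iks) * Cm / (Fdy * Vi);
    double b1 = (2.0 * inaca - ipca - ical - ibca) * Cm / (2.0 * Fdy * Vi) +
      (Vup * (iupleak - iup) + irel * Vrel) / Vi;
    double b2 = 1.0 + trpnmax * kmtrpn / sq(y[18] + kmtrpn) +
      cmdnmax * kmcmdn / sq(y[18] + kmcmdn);
    y[18] += dt * b1 / b2;
    if (y[18] < 1e-8) y[18] = 1e-8;
    y[19] += dt * (iup - iupleak - itr * Vrel / Vup);
    y[20] += dt * (itr - irel) /
      (1.0 + csqnmax * kmcsqn / sq(y[20] + kmcsqn));
    if (y[20] < 1e-8) y[20] = 1e-8;

    double itot = ina + ik1 + ito + ikur + ikr + iks + ical + ipca + inak +
      inaca + ibna + ibca;
    y[0] = V + dt * (-itot + istim);
  }
  return y[0];
}

// Nernst-level cache for a node: {ena, ek, eca, inak concentration factor}
inline void node_aux(const double* y, double* aux) {
  aux[0] = std::log(Nao / y[16]) / FRT;
  aux[1] = std::log(Ko / y[17]) / FRT;
  aux[2] = std::log(Cao / y[18]) / (2.0 * FRT);
  aux[3] = 1.0 / (1.0 + std::pow(kmnai / y[16], 1.5)) * (Ko / (Ko + kmko));
}

// shared table cache (single-threaded use)
Tables& tables_for(double dt_max);

} // namespace crn

#endif
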