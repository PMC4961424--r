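#include <Rcpp.h>
#include "crn_model.h"
using namespace Rcpp;

namespace crn {
Tables& tables_for(double dt_max) {
  static Tables tab;
  static double cur_dt = -1.0;
  if (cur_dt != dt_max) { tab.build(dt_max); cur_dt = dt_max; }
  return tab;
}
}

static void check_state(const NumericVector& y) {
  if (y.size() != crn::NSTATE)
    stop("ionic state must have %d components", crn::NSTATE);
  static const int gates[15] = {1,2,3,4,5,6,7,8,9,10,11,12,13,14,15};
  for (int k = 0; k < 15; ++k)
    if (y[gates[k]] < -1e-9 || y[gates[k]] > 1.0 + 1e-9)
      stop("gating variable %d outside [0,1]", gates[k]);
  for (int k = 16; k < 21; ++k)
    if (!(y[k] > 0)) stop("concentration %d must be positive", k);
}

// [[Rcpp::export]]
NumericVector cpp_crn_default_state() {
  NumericVector y(crn::NSTATE);
  crn::default_state(REAL(y));
  return y;
}

// Exact (table-free) evaluation of all currents, pA/pF.
// [[Rcpp::export]]
NumericVector cpp_crn_currents(NumericVector state, NumericVector scales) {
  check_state(state);
  double cur[14];
  crn::currents(REAL(state), REAL(scales), cur);
  NumericVector out(14);
  for (int k = 0; k < 14; ++k) out[k] = cur[k];
  out.attr("names") = CharacterVector::create(
    "INa", "IK1", "Ito", "IKur", "IKr", "IKs", "ICaL", "IpCa", "INaK",
    "INaCa", "IbNa", "IbCa", "Irel", "Fn");
  return out;
}

// One exact Rush-Larsen / forward-Euler reaction step of size dt.
// istim > 0 depolarizes (pA/pF).
// [[Rcpp::export]]
NumericVector cpp_crn_step_exact(NumericVector state, NumericVector scales,
                                 double istim, double dt) {
  check_state(state);
  NumericVector out = clone(state);
  double* y = REAL(out);
  const double* s = REAL(scales);
  double inf[12], tau[12], cur[14];
  crn::gate_rates(y[0], inf, tau);
  crn::currents(y, s, cur);
  double irel = cur[12], fn = cur[13];
  double itr = (y[19] - y[20]) / crn::tautr;
  double iup = crn::iupmax / (1.0 + crn::kup / y[18]);
  double iupleak = crn::iupmax * y[19] / crn::caupmax;
  static const int idx[12] = {1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 15};
  for (int g = 0; g < 12; ++g)
    y[idx[g]] = inf[g] + (y[idx[g]] - inf[g]) * std::exp(-dt / tau[g]);
  double fcainf = 1.0 / (1.0 + y[18] / 0.00035);
  y[12] = fcainf + (y[12] - fcainf) * std::exp(-dt / 2.0);
  double arg = (fn - 3.4175e-13) / 13.67e-16;
  double sg = arg > 35 ? 1.0 : (arg < -35 ? 0.0 : 1.0 / (1.0 + std::exp(-arg)));
  y[13] = sg + (y[13] - sg) * std::exp(-dt / 8.0);
  double tauv = 1.91 + 2.09 * sg;
  double arg2 = (fn - 6.835e-14) / 13.67e-16;
  double vinf = arg2 > 35 ? 0.0 : (arg2 < -35 ? 1.0
                 : 1.0 - 1.0 / (1.0 + std::exp(-arg2)));
  y[14] += dt * (vinf - y[14]) / tauv;
  y[16] += dt * (-3*cur[8] - 3*cur[9] - cur[10] - cur[0]) * crn::Cm /
    (crn::Fdy * crn::Vi);
  y[17] += dt * (2*cur[8] - cur[1] - cur[2] - cur[3] - cur[4] - cur[5]) *
    crn::Cm / (crn::Fdy * crn::Vi);
  double b1 = (2*cur[9] - cur[7] - cur[6] - cur[11]) * crn::Cm /
    (2.0 * crn::Fdy * crn::Vi) +
    (crn::Vup * (iupleak - iup) + irel * crn::Vrel) / crn::Vi;
  double b2 = 1.0 + crn::trpnmax * crn::kmtrpn / crn::sq(y[18] + crn::kmtrpn) +
    crn::cmdnmax * crn::kmcmdn / crn::sq(y[18] + crn::kmcmdn);
  y[18] += dt * b1 / b2;
  y[19] += dt * (iup - iupleak - itr * crn::Vrel / crn::Vup);
  y[20] += dt * (itr - irel) /
    (1.0 + crn::csqnmax * crn::kmcsqn / crn::sq(y[20] + crn::kmcsqn));
  double itot = cur[0]+cur[1]+cur[2]+cur[3]+cur[4]+cur[5]+cur[6]+cur[7]+
    cur[8]+cur[9]+cur[10]+cur[11];
  y[0] += dt * (-itot + istim);
  for (int k = 0; k < crn::NSTATE; ++k)
    if (!R_finite(y[k])) stop("integration failure in state component %d", k + 1);
  return out;
}

// Paced single-cell run with the tissue-grade adaptive integrator.
// Stimuli at t = 0, cl, 2*cl, ...; samples V every sample_dt ms.
// Returns list(t, V, state) where state is the final ionic state.
// [[Rcpp::export]]
List cpp_crn_pace(NumericVector state, NumericVector scales, double cl,
                  int n_beats, double amp, double dur, double duration,
                  double dt_max, double sample_dt) {
  check_state(state);
  crn::Tables& T = crn::tables_for(dt_max);
  NumericVector y = clone(state);
  double* yp = REAL(y);
  const double* s = REAL(scales);
  int nstep = (int)std::lround(duration / dt_max);
  int stride = (int)std::lround(sample_dt / dt_max);
  int nsamp = nstep / stride + 1;
  NumericVector tv(nsamp), vv(nsamp);
  double aux[4];
  crn::node_aux(yp, aux);
  double dvdt = 0.0;
  int is = 0;
  tv[0] = 0.0; vv[0] = yp[0]; is = 1;
  for (int k = 0; k < nstep; ++k) {
    double t = k * dt_max;
    if (k % 10 == 0) crn::node_aux(yp, aux);
    double beat = std::floor(t / cl);
    double istim = (beat < n_beats && (t - beat * cl) < dur) ? amp : 0.0;
    int bank = std::fabs(dvdt) > 10.0 ? 2 : (std::fabs(dvdt) > 1.0 ? 1 : 0);
    int nsub = bank == 2 ? 10 : (bank == 1 ? 2 : 1);
    double v0 = yp[0];
    double vnew;
    try {
      vnew = crn::step_node(yp, T, bank, nsub, s, istim, aux);
    } catch (std::exception& e) {
      stop("integration failure at t=%.3f ms: %s", t, e.what());
    }
    dvdt = (vnew - v0) / dt_max;
    if ((k + 1) % stride == 0 && is < nsamp) {
      tv[is] = (k + 1) * dt_max;
      vv[is] = yp[0];
      ++is;
    }
  }
  return List::create(_["t"] = tv, _["V"] = vv, _["state"] = y);
}
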