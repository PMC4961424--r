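// Monodomain reaction-diffusion stepper: explicit diffusion of V on a
// precomputed mass-lumped surface-Laplacian (CSR, diffusion coefficient
// folded into the weights), Rush-Larsen/forward-Euler reaction per node with
// per-node adaptive substepping (dt, dt/2, dt/10 banks keyed to |dV/dt|).
#include <Rcpp.h>
#include "crn_model.h"
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_tissue_run(NumericMatrix states, IntegerVector row_ptr,
                    IntegerVector col_idx, NumericVector vals,
                    NumericVector diag, LogicalVector conduct,
                    NumericVector scales, List stim_events,
                    double t0, double duration, double dt_max,
                    double record_interval, NumericMatrix record_windows,
                    bool reaction_on, Nullable<NumericVector> dvdt0) {
  const int N = states.ncol();
  if (states.nrow() != crn::NSTATE) stop("states must be 21 x N");
  crn::Tables& T = crn::tables_for(dt_max);
  const double* s = REAL(scales);

  // copy states into a working buffer (node-major)
  std::vector<double> Y(REAL(states), REAL(states) + (size_t)crn::NSTATE * N);

  // stimulus events
  const int nev = stim_events.size();
  std::vector<std::vector<int>> ev_nodes(nev);
  std::vector<double> ev_on(nev), ev_off(nev), ev_amp(nev);
  for (int e = 0; e < nev; ++e) {
    List ev = stim_events[e];
    IntegerVector nd = ev["nodes"];
    ev_nodes[e].assign(nd.begin(), nd.end());   // 1-based from R
    ev_on[e] = as<double>(ev["onset"]);
    ev_off[e] = ev_on[e] + as<double>(ev["duration"]);
    ev_amp[e] = as<double>(ev["amplitude"]);
  }

  const int nstep = (int)std::lround(duration / dt_max);
  const int stride = std::max(1, (int)std::lround(record_interval / dt_max));

  // which macro steps produce recorded frames
  auto in_window = [&](double t) {
    for (int w = 0; w < record_windows.nrow(); ++w)
      if (t >= record_windows(w, 0) - 1e-9 && t <= record_windows(w, 1) + 1e-9)
        return true;
    return false;
  };
  std::vector<int> frame_steps;
  for (int k = 0; k <= nstep; k += stride)
    if (in_window(t0 + k * dt_max)) frame_steps.push_back(k);
  NumericMatrix Vrec(N, (int)frame_steps.size());
  NumericVector trec((int)frame_steps.size());
  size_t next_frame = 0;

  std::vector<double> aux(4 * N), dvdt(N, 0.0), istim(N, 0.0);
  if (dvdt0.isNotNull()) {
    NumericVector d0(dvdt0);
    if (d0.size() == N) std::copy(d0.begin(), d0.end(), dvdt.begin());
  }
  std::vector<double> lap(N, 0.0);
  for (int i = 0; i < N; ++i) crn::node_aux(&Y[(size_t)crn::NSTATE * i], &aux[4 * i]);

  std::vector<int> act_nodes;
  std::vector<double> act_times;
  act_nodes.reserve(1024); act_times.reserve(1024);

  auto record = [&](int k) {
    if (next_frame < frame_steps.size() && frame_steps[next_frame] == k) {
      for (int i = 0; i < N; ++i) Vrec(i, (int)next_frame) = Y[(size_t)crn::NSTATE * i];
      trec[(int)next_frame] = t0 + k * dt_max;
      ++next_frame;
    }
  };
  record(0);

  for (int k = 0; k < nstep; ++k) {
    const double t = t0 + k * dt_max;
    // diffusion on V from a consistent snapshot
    for (int i = 0; i < N; ++i) {
      if (!conduct[i]) { lap[i] = 0.0; continue; }
      double acc = 0.0;
      for (int p = row_ptr[i]; p < row_ptr[i + 1]; ++p)
        acc += vals[p] * Y[(size_t)crn::NSTATE * col_idx[p]];
      lap[i] = acc - diag[i] * Y[(size_t)crn::NSTATE * i];
    }
    // stimulus
    std::fill(istim.begin(), istim.end(), 0.0);
    for (int e = 0; e < nev; ++e)
      if (t >= ev_on[e] - 1e-9 && t < ev_off[e] - 1e-9)
        for (int nd : ev_nodes[e]) istim[nd - 1] = ev_amp[e];

    const bool refresh = (k % 10 == 0);
    for (int i = 0; i < N; ++i) {
      if (!conduct[i]) continue;
      double* y = &Y[(size_t)crn::NSTATE * i];
      const double v0 = y[0];
      y[0] += dt_max * lap[i];
      if (reaction_on) {
        if (refresh) crn::node_aux(y, &aux[4 * i]);
        const double ad = std::fabs(dvdt[i]);
        const int bank = ad > 10.0 ? 2 : (ad > 1.0 ? 1 : 0);
        const int nsub = bank == 2 ? 10 : (bank == 1 ? 2 : 1);
        try {
          crn::step_node(y, T, bank, nsub, s, istim[i], &aux[4 * i]);
        } catch (std::exception& e) {
          stop("simulation blow-up at t=%.3f ms, node %d", t, i + 1);
        }
      }
      dvdt[i] = (y[0] - v0) / dt_max;
      if (v0 < -40.0 && y[0] >= -40.0) {
        act_nodes.push_back(i + 1);
        act_times.push_back(t + dt_max);
      }
      if (std::fabs(y[0]) > 300.0)
        stop("simulation blow-up at t=%.3f ms, node %d", t, i + 1);
    }
    record(k + 1);
  }

  NumericMatrix out_states(crn::NSTATE, N);
  std::copy(Y.begin(), Y.end(), REAL(out_states));
  return List::create(
    _["t"] = trec, _["V"] = Vrec,
    _["act_node"] = wrap(act_nodes), _["act_time"] = wrap(act_times),
    _["state"] = out_states, _["dvdt"] = wrap(dvdt));
}
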