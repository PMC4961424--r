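#' @useDynLib afsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.afsim_cache <- new.env(parent = emptyenv())

.state_names <- c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                  "d", "f", "fca", "u", "v", "w",
                  "Nai", "Ki", "Cai", "Caup", "Carel")

#' Ionic remodeling parameters
#'
#' Multipliers applied to the maximal conductances of four currents of the
#' Courtemanche human atrial myocyte model. The `"af_remodeled"` preset
#' carries the electrical remodeling of persistent AF: Ito reduced by 80%,
#' IKur by 50%, ICaL by 40%, and IK1 increased by 50%. `"baseline"` is the
#' unmodified model.
#'
#' @param scale_Ito,scale_IKur,scale_ICaL,scale_IK1 positive multipliers.
#' @return an object of class `remodeling_params` (named numeric of length 4).
#' @export
remodeling_params <- function(scale_Ito = 1, scale_IKur = 1,
                              scale_ICaL = 1, scale_IK1 = 1) {
  s <- c(Ito = scale_Ito, IKur = scale_IKur, ICaL = scale_ICaL,
         IK1 = scale_IK1)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("all remodeling scales must be positive", call. = FALSE)
  structure(s, class = "remodeling_params")
}

#' @rdname remodeling_params
#' @param name preset name, `"baseline"` or `"af_remodeled"`.
#' @export
remodeling_preset <- function(name = c("af_remodeled", "baseline")) {
  name <- match.arg(name)
  if (name == "baseline") remodeling_params()
  else remodeling_params(0.2, 0.5, 0.6, 1.5)
}

.scales <- function(remodeling) {
  stopifnot(inherits(remodeling, "remodeling_params"))
  as.numeric(remodeling)
}

#' Resting (equilibrium) ionic state
#'
#' Integrates the unstimulated cell from the published initial conditions
#' until the membrane potential is stationary. Results are cached per
#' remodeling parameter set, so repeated calls are cheap and identical.
#'
#' @param remodeling a [remodeling_params()] object.
#' @param settle_ms quiescent integration time (ms).
#' @return named numeric vector of class `ionic_state` (21 components).
#' @export
resting_state <- function(remodeling = remodeling_preset("baseline"),
                          settle_ms = 10000) {
  key <- paste0("rest_", paste(format(.scales(remodeling), digits = 12),
                               collapse = "_"), "_", settle_ms)
  if (!is.null(.afsim_cache[[key]])) return(.afsim_cache[[key]])
  out <- cpp_crn_pace(cpp_crn_default_state(), .scales(remodeling),
                      cl = settle_ms * 2, n_beats = 0, amp = 0, dur = 0,
                      duration = settle_ms, dt_max = 0.05, sample_dt = 100)
  st <- as.numeric(out$state)
  names(st) <- .state_names
  v <- out$V
  n <- length(v)
  drift <- abs(v[n] - v[n - 1]) / 100  # mV/ms over the final 100 ms
  if (drift > 0.01)
    stop("resting state did not converge (|dV/dt| = ", signif(drift, 3),
         " mV/ms after ", settle_ms, " ms)", call. = FALSE)
  st <- structure(st, class = "ionic_state")
  .afsim_cache[[key]] <- st
  st
}

#' Transmembrane ionic currents at a state
#'
#' Evaluates every membrane current of the Courtemanche model (pA/pF) at the
#' given state, with the remodeling multipliers applied to Ito, IKur, ICaL
#' and IK1. Also returns the SR release flux and the total membrane current.
#'
#' @param state an `ionic_state` vector.
#' @inheritParams resting_state
#' @return list with `total` (pA/pF) and `currents` (named vector).
#' @export
ionic_current <- function(state, remodeling = remodeling_preset("baseline")) {
  cur <- cpp_crn_currents(as.numeric(state), .scales(remodeling))
  membrane <- cur[c("INa", "IK1", "Ito", "IKur", "IKr", "IKs", "ICaL",
                    "IpCa", "INaK", "INaCa", "IbNa", "IbCa")]
  list(total = sum(membrane), currents = cur)
}

#' Advance a single cell by one reaction step
#'
#' One Rush-Larsen (gates) / forward-Euler (potential and concentrations)
#' step of size `dt`. Positive `i_stim` depolarizes.
#'
#' @param state an `ionic_state` vector.
#' @inheritParams resting_state
#' @param i_stim stimulus current (pA/pF), positive depolarizing.
#' @param dt time step (ms), within \[0.005, 0.05\].
#' @return the advanced `ionic_state`.
#' @export
step_cell <- function(state, remodeling = remodeling_preset("baseline"),
                      i_stim = 0, dt = 0.05) {
  if (dt < 0.005 - 1e-12 || dt > 0.05 + 1e-12)
    stop("dt must lie in [0.005, 0.05] ms", call. = FALSE)
  out <- cpp_crn_step_exact(as.numeric(state), .scales(remodeling), i_stim, dt)
  names(out) <- .state_names
  structure(out, class = "ionic_state")
}

#' Diastolic stimulus threshold
#'
#' Minimal 2-ms stimulus amplitude (pA/pF) that elicits an action potential
#' (V exceeding 0 mV within 20 ms) from rest, found by bisection and cached
#' per remodeling preset.
#'
#' @inheritParams resting_state
#' @param stim_duration stimulus duration (ms).
#' @return threshold amplitude (pA/pF).
#' @export
stim_threshold <- function(remodeling = remodeling_preset("baseline"),
                           stim_duration = 2) {
  key <- paste0("thr_", paste(format(.scales(remodeling), digits = 12),
                              collapse = "_"), "_", stim_duration)
  if (!is.null(.afsim_cache[[key]])) return(.afsim_cache[[key]])
  rest <- resting_state(remodeling)
  fires <- function(amp) {
    out <- cpp_crn_pace(as.numeric(rest), .scales(remodeling), cl = 1000,
                        n_beats = 1, amp = amp, dur = stim_duration,
                        duration = 20, dt_max = 0.05, sample_dt = 0.5)
    max(out$V) > 0
  }
  lo <- 0.5; hi <- 64
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 1024) stop("no capture at any stimulus amplitude", call. = FALSE)
  }
  for (k in 1:12) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  .afsim_cache[[key]] <- hi
  hi
}

#' Pace a single cell and record the action potential
#'
#' Paces from the resting state at a fixed cycle length with the adaptive
#' integrator (macro step 0.05 ms, substeps down to 0.005 ms during fast
#' phases) and returns a uniformly sampled voltage trace.
#'
#' @inheritParams resting_state
#' @param cycle_length pacing cycle length (ms).
#' @param n_beats number of stimuli (>= 1).
#' @param stim_amplitude stimulus amplitude (pA/pF); default twice the
#'   diastolic threshold.
#' @param stim_duration stimulus duration (ms).
#' @param sample_dt trace sampling interval (ms).
#' @param extra_ms extra unpaced time appended after the last cycle.
#' @return an `ap_trace`: list with `t` (ms), `V` (mV), `stim_times` (ms).
#' @export
pace_cell <- function(remodeling = remodeling_preset("baseline"),
                      cycle_length = 1000, n_beats = 5,
                      stim_amplitude = NULL, stim_duration = 2,
                      sample_dt = 1, extra_ms = 0) {
  stopifnot(n_beats >= 1)
  if (is.null(stim_amplitude))
    stim_amplitude <- 2 * stim_threshold(remodeling, stim_duration)
  rest <- resting_state(remodeling)
  out <- cpp_crn_pace(as.numeric(rest), .scales(remodeling),
                      cl = cycle_length, n_beats = n_beats,
                      amp = stim_amplitude, dur = stim_duration,
                      duration = n_beats * cycle_length + extra_ms,
                      dt_max = 0.05, sample_dt = sample_dt)
  stim_times <- (seq_len(n_beats) - 1) * cycle_length
  captured <- vapply(stim_times, function(s)
    any(out$V[out$t >= s & out$t <= s + 20] > 0), TRUE)
  structure(list(t = out$t, V = out$V, captured = captured,
                 stim_times = stim_times,
                 final_state = structure(stats::setNames(
                   as.numeric(out$state), .state_names), class = "ionic_state")),
            class = "ap_trace")
}

#' Write an action-potential trace to CSV
#'
#' Two columns: `time_ms`, `V_mV`.
#'
#' @param trace an `ap_trace`.
#' @param path output file.
#' @export
write_ap_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$t, V_mV = trace$V), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Action potential duration at 90% repolarization
#'
#' APD90 of the last fully repolarized beat: time from the maximum-dV/dt
#' instant of the upstroke to the crossing of
#' `V_peak - 0.9 * (V_peak - V_diastolic)`, where the peak is the beat's own
#' maximum and the diastolic potential is taken just before the upstroke.
#' Crossings are linearly interpolated between samples.
#'
#' @param trace an `ap_trace` (or any list with `t` and `V`).
#' @param dvdt_min upstroke detection threshold on dV/dt (mV/ms).
#' @return APD90 in ms.
#' @export
measure_apd90 <- function(trace, dvdt_min = 10) {
  t <- trace$t; v <- trace$V
  if (length(t) < 3) stop("trace too short", call. = FALSE)
  dv <- diff(v) / diff(t)
  fast <- which(dv > dvdt_min)
  if (!length(fast))
    stop("APD90 undefined: no action potential in trace", call. = FALSE)
  starts <- fast[c(TRUE, diff(fast) > 5)]
  for (s in rev(starts)) {
    seg <- s:length(v)
    # maximum-dV/dt instant within this upstroke
    up_end <- min(s + 20, length(dv))
    imax <- (s:up_end)[which.max(dv[s:up_end])]
    t_up <- t[imax]
    vpk <- max(v[seg]); ipk <- seg[which.max(v[seg])]
    vdia <- v[max(1, s - 5)]
    v90 <- vpk - 0.9 * (vpk - vdia)
    tail_idx <- ipk:length(v)
    below <- which(v[tail_idx] <= v90)
    if (length(below)) {
      i2 <- tail_idx[below[1]]
      if (i2 == ipk) return(t[i2] - t_up)
      frac <- (v[i2 - 1] - v90) / (v[i2 - 1] - v[i2])
      return(t[i2 - 1] + frac * (t[i2] - t[i2 - 1]) - t_up)
    }
  }
  stop("APD90 undefined: no complete repolarization in trace", call. = FALSE)
}

#' @export
print.ionic_state <- function(x, ...) {
  cat("<ionic_state> V =", format(x[["V"]], digits = 6), "mV\n")
  invisible(x)
}

#' @export
print.ap_trace <- function(x, ...) {
  cat("<ap_trace>", length(x$t), "samples,",
      format(max(x$t), digits = 6), "ms,", length(x$stim_times), "stimuli\n")
  invisible(x)
}
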