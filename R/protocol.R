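# AF induction by ramp ("straight") pacing from the high-septal region,
# activity detection, and rhythm classification (AF / AT / quiescent).

#' Straight (ramp) pacing protocol
#'
#' Consecutive pacing trains at cycle lengths of 200, 190 and 180 ms
#' delivered to a small patch in the high septum (region R1). Eight beats
#' per cycle length give the canonical 4560-ms total.
#'
#' @param mesh a labeled `surface_mesh`.
#' @param site_label region holding the stimulus site (default R1, septum).
#' @param beats_per_cl beats per cycle length.
#' @param cycle_lengths pacing cycle lengths (ms).
#' @param site_radius stimulus patch radius (mm).
#' @param amplitude stimulus amplitude (pA/pF); default 4x the diastolic
#'   threshold of the AF-remodeled cell.
#' @param stim_duration stimulus duration (ms).
#' @return a `pacing_protocol`: list of stimulus events plus bookkeeping.
#' @export
straight_pacing <- function(mesh, site_label = 1, beats_per_cl = 8,
                            cycle_lengths = c(200, 190, 180),
                            site_radius = 8, amplitude = NULL,
                            stim_duration = 2) {
  stopifnot(beats_per_cl >= 1)
  cand <- which(mesh$region == site_label)
  if (!length(cand)) stop("no nodes carry the stimulus-site label",
                          call. = FALSE)
  # "high" septum: the most superior node of the section
  center <- cand[which.max(mesh$vertices[cand, 3])]
  d2 <- rowSums(sweep(mesh$vertices, 2, mesh$vertices[center, ])^2)
  site <- which(d2 <= site_radius^2)
  if (is.null(amplitude))
    amplitude <- 4 * stim_threshold(remodeling_preset("af_remodeled"))
  events <- list()
  t <- 0
  for (cl in cycle_lengths) {
    for (b in seq_len(beats_per_cl)) {
      events[[length(events) + 1]] <-
        stimulus_event(site, t, stim_duration, amplitude)
      t <- t + cl
    }
  }
  structure(list(events = events, total_ms = t, site = site,
                 cycle_lengths = cycle_lengths,
                 beats_per_cl = beats_per_cl), class = "pacing_protocol")
}

#' @export
print.pacing_protocol <- function(x, ...) {
  cat("<pacing_protocol>", length(x$events), "stimuli over", x$total_ms,
      "ms at CLs", paste(x$cycle_lengths, collapse = "/"), "ms,",
      length(x$site), "site nodes\n")
  invisible(x)
}

#' Induce AF and follow the episode
#'
#' Runs the pacing protocol, then follows the unpaced activity up to
#' `follow_ms`, recording membrane potential inside the requested DF
#' analysis windows and emitting a full-state checkpoint at the end of each
#' window (ablation trials branch from these). The episode stops early if
#' activity ceases (self-termination).
#'
#' @param op a `diffusion_operator`.
#' @inheritParams tissue_state
#' @param protocol a [straight_pacing()] protocol.
#' @param follow_ms unpaced follow-up after the end of pacing (ms).
#' @param windows k x 2 matrix of absolute DF-window times (ms), or NULL.
#' @param record_interval V sampling interval inside windows (ms).
#' @param quiet_ms activity gap (ms) that declares self-termination.
#' @return an `af_episode`: recording (window frames + all activation
#'   events), per-window checkpoints, `induced` flag and
#'   `self_termination_ms` (NA if sustained).
#' @export
induce_af <- function(op, remodeling = remodeling_preset("af_remodeled"),
                      protocol, follow_ms = 30000, windows = NULL,
                      record_interval = 1, quiet_ms = 200) {
  pace_end <- protocol$total_ms
  t_end <- pace_end + follow_ms
  if (is.null(windows)) windows <- matrix(numeric(0), 0, 2)
  # segment boundaries: end of pacing, each window edge, 1-s grid for early
  # termination checks
  brk <- sort(unique(c(pace_end, as.vector(windows), t_end,
                       seq(pace_end, t_end, by = 1000))))
  brk <- brk[brk > 0 & brk <= t_end]
  state <- NULL
  t_prev <- 0
  all_events <- list()
  frames_t <- list(); frames_v <- list()
  checkpoints <- vector("list", nrow(windows))
  terminated_at <- NA_real_
  last_event <- 0
  for (b in brk) {
    rec <- run_simulation(op, remodeling, duration = b - t_prev,
                          state = state, stimuli = protocol$events,
                          record_interval = record_interval,
                          record_windows = windows)
    state <- attr(rec, "final_state")
    all_events[[length(all_events) + 1]] <- rec$events
    if (length(rec$t)) {
      frames_t[[length(frames_t) + 1]] <- rec$t
      frames_v[[length(frames_v) + 1]] <- rec$V
    }
    if (nrow(rec$events)) last_event <- max(last_event, max(rec$events$time_ms))
    wi <- which(abs(windows[, 2] - b) < 1e-9)
    if (length(wi)) for (w in wi) checkpoints[[w]] <- state
    if (b > pace_end && b - last_event >= quiet_ms) {
      terminated_at <- last_event
      break
    }
    t_prev <- b
  }
  events <- do.call(rbind, all_events)
  recording <- structure(list(
    t = if (length(frames_t)) do.call(c, frames_t) else numeric(0),
    V = if (length(frames_v)) do.call(cbind, frames_v) else
      matrix(0, length(op$diag), 0),
    events = events, t0 = 0, t1 = if (is.na(terminated_at)) t_end else
      terminated_at, record_interval = record_interval,
    n_nodes = length(op$diag), conduct = op$conduct),
    class = "ap_recording")
  induced <- any(events$time_ms >= pace_end + 2000)
  structure(list(recording = recording, checkpoints = checkpoints,
                 windows = windows, induced = induced,
                 self_termination_ms = terminated_at,
                 pace_end = pace_end, final_state = state),
            class = "af_episode")
}

#' @export
print.af_episode <- function(x, ...) {
  cat("<af_episode> pacing to", x$pace_end, "ms,",
      if (x$induced) "induced," else "not induced,",
      if (is.na(x$self_termination_ms)) "sustained"
      else paste("self-terminated at", round(x$self_termination_ms), "ms"),
      "\n")
  invisible(x)
}

#' Fraction of conducting nodes active in a window
#'
#' A node is active if it shows at least one upstroke (-40 mV crossing with
#' positive dV/dt) inside the window.
#'
#' @param recording an `ap_recording` (activation events cover the run).
#' @param window numeric (start, end) ms.
#' @export
detect_activity <- function(recording, window) {
  if (window[2] <= window[1]) stop("empty window", call. = FALSE)
  conduct <- recording$conduct %||% rep(TRUE, recording$n_nodes)
  ev <- recording$events
  act <- unique(ev$node[ev$time_ms >= window[1] & ev$time_ms < window[2]])
  length(intersect(act, which(conduct))) / sum(conduct)
}

#' Classify the rhythm in a window
#'
#' QUIESCENT if no conducting node activates during the final second of the
#' window. Otherwise the rhythm is probed at 20 area-stratified random
#' nodes (seeded, hence deterministic): if at least 90% of the probes have
#' a regular activation sequence (inter-activation-interval coefficient of
#' variation < 10%) and the probe DFs agree within one frequency bin, the
#' rhythm is organized atrial tachycardia (AT); otherwise AF.
#'
#' @param recording an `ap_recording`; V frames must cover the window for
#'   the DF concordance check (events alone suffice for QUIESCENT).
#' @param window numeric (start, end) ms, at least 2 s long.
#' @param mesh the mesh (for probe area stratification).
#' @param n_probes number of probe nodes.
#' @param cov_limit regularity threshold (%).
#' @param probe_quorum fraction of probes required for AT.
#' @param seed probe-selection seed.
#' @return a `rhythm_label`: list with `label` in {AF, AT, QUIESCENT} and
#'   the evidence (mean CL, CL CoV, active fraction, probe ids).
#' @export
classify_rhythm <- function(recording, window, mesh, n_probes = 20,
                            cov_limit = 10, probe_quorum = 0.9, seed = 1) {
  if (window[2] - window[1] < 2000 - 1e-9)
    stop("classification window must be at least 2 s", call. = FALSE)
  conduct <- recording$conduct %||% rep(TRUE, recording$n_nodes)
  ev <- recording$events
  final_act <- detect_activity(recording, c(window[2] - 1000, window[2]))
  if (final_act == 0) {
    lab <- list(label = "QUIESCENT", mean_cl_ms = NA_real_,
                cl_cov_pct = NA_real_, active_fraction = 0, probes = integer(0))
    return(structure(lab, class = "rhythm_label"))
  }
  probes <- .stratified_probes(mesh, conduct, n_probes, seed)
  st <- .probe_regularity(ev, probes, window)
  # DF concordance among regular probes
  df_ok <- TRUE
  covered <- length(recording$t) &&
    any(recording$t >= window[1] & recording$t < window[2])
  if (covered) {
    dm <- compute_df_map(recording, window)
    dfs <- dm$df[probes]
    dfs <- dfs[!is.na(dfs)]
    df_ok <- length(dfs) > 0 &&
      (max(dfs) - min(dfs)) <= dm$resolution + 1e-9
  }
  regular <- mean(st$cov < cov_limit, na.rm = TRUE)
  regular[is.na(regular)] <- 0
  label <- if (regular >= probe_quorum && df_ok) "AT" else "AF"
  structure(list(label = label,
                 mean_cl_ms = mean(st$mean_cl, na.rm = TRUE),
                 cl_cov_pct = mean(st$cov, na.rm = TRUE),
                 active_fraction = detect_activity(recording, window),
                 probes = probes), class = "rhythm_label")
}

# area-weighted random probe selection with an isolated RNG stream
.stratified_probes <- function(mesh, conduct, n_probes, seed) {
  cand <- which(conduct)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  sample(cand, min(n_probes, length(cand)), prob = mesh$area[cand])
}

# per-probe inter-activation statistics within a window
.probe_regularity <- function(events, probes, window) {
  res <- vapply(probes, function(p) {
    tt <- events$time_ms[events$node == p & events$time_ms >= window[1] &
                           events$time_ms < window[2]]
    if (length(tt) < 3) return(c(NA_real_, NA_real_))
    iv <- diff(tt)
    c(mean(iv), 100 * stats::sd(iv) / mean(iv))
  }, numeric(2))
  list(mean_cl = res[1, ], cov = res[2, ])
}

#' @export
print.rhythm_label <- function(x, ...) {
  cat("<rhythm_label>", x$label,
      if (!is.na(x$mean_cl_ms)) paste0("(mean CL ",
                                       round(x$mean_cl_ms), " ms, CoV ",
                                       round(x$cl_cov_pct, 1), "%)") else "",
      "\n")
  invisible(x)
}
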