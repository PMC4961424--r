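# Monodomain propagation: dV/dt = D lap(V) - (Iion + Istim)/Cm on a
# triangulated surface, with the diffusion term discretized as a
# cotangent-weighted Laplace-Beltrami operator under barycentric lumped
# mass, and the reaction term given by the Courtemanche cell model.

#' Diffusion field
#'
#' Homogeneous scalar diffusion coefficient plus a per-node conduction mask
#' (FALSE = non-conducting, e.g. ablated tissue).
#'
#' @param D diffusion coefficient (mm^2/ms).
#' @param conduct logical per-node conduction mask, or NULL for all-conducting.
#' @param Cm membrane capacitance (pF), fixed by the cell model.
#' @return a `diffusion_field`.
#' @export
diffusion_field <- function(D, conduct = NULL, Cm = 100) {
  stopifnot(D >= 0)
  structure(list(D = D, conduct = conduct, Cm = Cm),
            class = "diffusion_field")
}

#' Build the surface diffusion operator
#'
#' Assembles the cotangent-weighted Laplace-Beltrami operator with
#' barycentric lumped mass on the mesh, folds in the diffusion coefficient,
#' and zeroes all couplings of non-conducting nodes (total conduction
#' block). Rows sum to zero over conducting nodes, which realizes no-flux
#' boundaries. Negative cotangent weights (obtuse triangle pairs) are
#' clamped to zero.
#'
#' @param mesh a `surface_mesh`.
#' @param field a [diffusion_field()].
#' @return a `diffusion_operator` carrying the mesh, field and sparse
#'   structure used by the solver.
#' @export
build_diffusion_operator <- function(mesh, field) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(field, "diffusion_field"))
  n <- nrow(mesh$vertices)
  conduct <- field$conduct %||% rep(TRUE, n)
  stopifnot(length(conduct) == n)
  v <- mesh$vertices; f <- mesh$faces
  cot_at <- function(p, q, r) {  # cotangent of angle at p in triangle pqr
    u <- v[q, , drop = FALSE] - v[p, , drop = FALSE]
    w <- v[r, , drop = FALSE] - v[p, , drop = FALSE]
    d <- rowSums(u * w)
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    d / pmax(sqrt(cx^2 + cy^2 + cz^2), 1e-12)
  }
  # edge (q,r) gets cot of the opposite angle at p
  ii <- c(f[, 2], f[, 3], f[, 1]); jj <- c(f[, 3], f[, 1], f[, 2])
  ww <- c(cot_at(f[, 1], f[, 2], f[, 3]),
          cot_at(f[, 2], f[, 3], f[, 1]),
          cot_at(f[, 3], f[, 1], f[, 2])) / 2
  clamped <- ww < 0
  if (mean(clamped) > 0.15)
    warning(sprintf("%.1f%% of cotangent weights negative; clamped to 0",
                    100 * mean(clamped)), call. = FALSE)
  ww[clamped] <- 0
  # symmetric weight matrix (both half-edges accumulate)
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  # mask non-conducting nodes entirely
  keep <- which(conduct)
  if (any(!conduct)) {
    W[!conduct, ] <- 0
    W[, !conduct] <- 0
    W <- Matrix::drop0(W)
  }
  A <- field$D * Matrix::Diagonal(x = 1 / mesh$area) %*% W  # rows by 1/m_i
  Ar <- as(A, "RsparseMatrix")
  diag_v <- Matrix::rowSums(A)
  # largest macro step satisfying the CFL-type bound D*dt*max(diag) < 0.5,
  # restricted to the admissible range [0.005, 0.05] ms
  stable_dt <- if (max(diag_v) > 0) 0.5 / max(diag_v) else Inf
  dt_grid <- c(0.05, 0.025, 0.01, 0.005)
  ok <- dt_grid[dt_grid < stable_dt]
  if (!length(ok))
    stop("CFL stability violated at the smallest admissible step: ",
         "D * 0.005 * max(diagonal) = ", signif(0.005 * max(diag_v), 3),
         " >= 0.5; reduce D or coarsen the mesh", call. = FALSE)
  if (length(keep) > 1) {
    e <- unique(mesh_edges(mesh))
    e <- e[conduct[e[, 1]] & conduct[e[, 2]], , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    comp <- igraph::components(g)
    if (length(unique(comp$membership[keep])) > 1)
      warning("conducting subgraph is disconnected", call. = FALSE)
  }
  structure(list(mesh = mesh, field = field, conduct = conduct,
                 row_ptr = Ar@p, col_idx = Ar@j, vals = Ar@x,
                 diag = as.numeric(diag_v), W = W, dt_max = ok[1]),
            class = "diffusion_operator")
}

#' Apply the diffusion operator to a nodal field
#'
#' Returns `D * lap(V)` per node (mV/ms for V in mV); used for solver
#' verification.
#'
#' @param op a `diffusion_operator`.
#' @param values numeric per-node vector.
#' @export
apply_diffusion <- function(op, values) {
  n <- length(op$diag)
  stopifnot(length(values) == n)
  res <- op$field$D * as.numeric(op$W %*% values) / op$mesh$area -
    op$diag * values
  as.numeric(res)
}

#' Stimulus event
#'
#' @param nodes node ids receiving the stimulus.
#' @param onset onset time (ms, absolute).
#' @param duration duration (ms, > 0).
#' @param amplitude amplitude (pA/pF), positive depolarizing.
#' @export
stimulus_event <- function(nodes, onset, duration = 2, amplitude = 40) {
  stopifnot(length(nodes) > 0, duration > 0)
  list(nodes = as.integer(nodes), onset = onset, duration = duration,
       amplitude = amplitude)
}

#' Initial tissue state (all nodes at rest)
#'
#' @param op a `diffusion_operator`.
#' @param remodeling a [remodeling_params()].
#' @return a `tissue_state`: list with the 21 x N state matrix, time, and
#'   the per-node dV/dt memory of the adaptive stepper.
#' @export
tissue_state <- function(op, remodeling = remodeling_preset("af_remodeled")) {
  n <- length(op$diag)
  rest <- as.numeric(resting_state(remodeling))
  structure(list(states = matrix(rest, nrow = 21, ncol = n), t = 0,
                 dvdt = numeric(n)), class = "tissue_state")
}

#' Advance tissue by one macro time step
#'
#' Explicit diffusion of V followed by the adaptive reaction update.
#'
#' @param state a `tissue_state`.
#' @param op a `diffusion_operator`.
#' @inheritParams tissue_state
#' @param stimuli list of [stimulus_event()]s (absolute onsets).
#' @param dt macro step (ms) in \[0.005, 0.05\].
#' @return the advanced `tissue_state`.
#' @export
step_tissue <- function(state, op, remodeling = remodeling_preset("af_remodeled"),
                        stimuli = list(), dt = 0.05) {
  if (dt < 0.005 - 1e-12 || dt > 0.05 + 1e-12)
    stop("dt must lie in [0.005, 0.05] ms", call. = FALSE)
  out <- run_simulation(op, remodeling, duration = dt, state = state,
                        stimuli = stimuli, record_interval = dt, dt_max = dt)
  attr(out, "final_state")
}

#' Run a monodomain simulation
#'
#' Advances the tissue for `duration` ms, recording the membrane potential
#' of every node at `record_interval` within the requested `record_windows`
#' (default: the whole run) and logging every upstroke (-40 mV crossing
#' with positive dV/dt) as an activation event. The returned recording also
#' carries the full final state, which serves as a restartable checkpoint.
#'
#' @param op a `diffusion_operator`.
#' @inheritParams step_tissue
#' @param duration simulated time (ms).
#' @param state optional starting `tissue_state` (default: all at rest).
#' @param record_interval sampling interval for V frames (ms).
#' @param record_windows k x 2 matrix of absolute (start, end) times, or
#'   NULL to record the whole run.
#' @param dt_max macro time step (ms); reaction substeps go down to
#'   `dt_max/10` wherever |dV/dt| is large.
#' @param reaction FALSE runs pure diffusion (solver verification).
#' @return an `ap_recording`: list with `t`, `V` (nodes x frames),
#'   `events` (activation data frame), and attribute `final_state`.
#' @export
run_simulation <- function(op, remodeling = remodeling_preset("af_remodeled"),
                           duration, state = NULL, stimuli = list(),
                           record_interval = 1, record_windows = NULL,
                           dt_max = NULL, reaction = TRUE) {
  stopifnot(inherits(op, "diffusion_operator"), duration > 0)
  dt_max <- min(dt_max %||% 0.05, op$dt_max)
  if (is.null(state)) state <- tissue_state(op, remodeling)
  t0 <- state$t
  if (is.null(record_windows))
    record_windows <- matrix(c(t0, t0 + duration), 1)
  res <- cpp_tissue_run(state$states, op$row_ptr, op$col_idx, op$vals,
                        op$diag, op$conduct, as.numeric(remodeling),
                        stimuli, t0, duration, dt_max, record_interval,
                        record_windows, reaction, state$dvdt)
  rec <- structure(list(
    t = res$t, V = res$V,
    events = data.frame(node = res$act_node, time_ms = res$act_time),
    t0 = t0, t1 = t0 + duration, record_interval = record_interval,
    n_nodes = length(op$diag), conduct = op$conduct), class = "ap_recording")
  attr(rec, "final_state") <- structure(
    list(states = res$state, t = t0 + duration, dvdt = res$dvdt),
    class = "tissue_state")
  rec
}

#' @export
print.ap_recording <- function(x, ...) {
  cat("<ap_recording>", x$n_nodes, "nodes,", length(x$t), "frames,",
      nrow(x$events), "activations, t =", x$t0, "..", x$t1, "ms\n")
  invisible(x)
}

#' Save / load a recording or checkpoint
#'
#' Recordings and tissue-state checkpoints are persisted as RDS containers
#' (R's native serialized binary format).
#'
#' @param object recording or `tissue_state`.
#' @param path file path.
#' @export
save_recording <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_recording
#' @export
load_recording <- function(path) readRDS(path)

#' Measure conduction velocity between two probes
#'
#' Activation time at a probe is its first upstroke (-40 mV crossing) after
#' `after_ms`; CV is inter-probe distance over activation-time difference.
#'
#' @param recording an `ap_recording` with activation events.
#' @param mesh the mesh the recording was made on.
#' @param probes two node ids, ordered along the propagation direction.
#' @param after_ms consider only activations after this time (to skip
#'   conditioning beats).
#' @return conduction velocity in m/s (= mm/ms).
#' @export
measure_cv <- function(recording, mesh, probes, after_ms = 0) {
  stopifnot(length(probes) == 2)
  d <- sqrt(sum((mesh$vertices[probes[1], ] - mesh$vertices[probes[2], ])^2))
  if (d < 1e-9) stop("probes are co-located", call. = FALSE)
  tact <- vapply(probes, function(p) {
    tt <- recording$events$time_ms[recording$events$node == p &
                                     recording$events$time_ms >= after_ms]
    if (!length(tt)) stop("probe node ", p, " never activated", call. = FALSE)
    tt[1]
  }, 0)
  dt <- tact[2] - tact[1]
  if (dt <= 0) stop("probes activated out of order", call. = FALSE)
  d / dt
}

# Package default diffusion coefficient (mm^2/ms) for the reference strip
# resolution of 0.25 mm, calibrated to CV = 0.4 m/s with the AF-remodeled
# cell (see calibrate_diffusion).
.default_D_025 <- 0.0822

#' Default calibrated diffusion coefficient
#'
#' The package's delivered diffusion coefficient for a given mesh edge
#' length, calibrated so a planar wave in AF-remodeled tissue travels at
#' 0.4 m/s. The value for the reference 0.25-mm strip is precalibrated;
#' other resolutions trigger a calibration run (cached).
#'
#' @param resolution mesh edge length (mm).
#' @param target_cv target conduction velocity (m/s).
#' @export
default_diffusion <- function(resolution = 0.25, target_cv = 0.4) {
  if (abs(resolution - 0.25) < 1e-9 && abs(target_cv - 0.4) < 1e-9)
    return(.default_D_025)
  calibrate_diffusion(target_cv, resolution)$D
}

#' Conduction-velocity measurement on a calibration strip
#'
#' Builds a 25 mm x 2.5 mm planar strip at the given edge length, paces one
#' end at 500-ms cycle length for `n_beats` beats, and measures CV between
#' two mid-line probes 10 mm apart after the conditioning beats.
#'
#' @param D diffusion coefficient (mm^2/ms).
#' @param resolution strip edge length (mm).
#' @inheritParams tissue_state
#' @param n_beats total beats (the last one is measured).
#' @return list with `cv` (m/s) and the probe ids.
#' @export
strip_cv <- function(D, resolution = 0.25,
                     remodeling = remodeling_preset("af_remodeled"),
                     n_beats = 3) {
  nx <- round(25 / resolution) + 1
  ny <- max(3, round(2.5 / resolution) + 1)
  mesh <- make_sheet(nx, ny, resolution)
  op <- build_diffusion_operator(mesh, diffusion_field(D))
  mid <- (ceiling(ny / 2) - 1) * nx
  probe_x <- c(round(7.5 / resolution), round(17.5 / resolution))
  probes <- mid + probe_x + 1
  # a ~1-mm-wide electrode band; a bare edge column is drained by diffusion
  pace_nodes <- which(mesh$vertices[, 1] <= max(1, resolution) + 1e-9)
  amp <- 4 * stim_threshold(remodeling)
  stimuli <- lapply(seq_len(n_beats) - 1,
                    function(b) stimulus_event(pace_nodes, b * 500, 2, amp))
  rec <- run_simulation(op, remodeling, duration = (n_beats - 1) * 500 + 250,
                        stimuli = stimuli, record_interval = 5)
  cv <- measure_cv(rec, mesh, probes, after_ms = (n_beats - 1) * 500)
  list(cv = cv, probes = probes, mesh = mesh)
}

#' Calibrate the diffusion coefficient to a target conduction velocity
#'
#' Iterates on D (using the CV ~ sqrt(D) scaling for updates, falling back
#' to bisection) until the strip CV is within `tol` of the target. Results
#' are cached per (target, resolution, remodeling).
#'
#' @param target_cv target CV (m/s), e.g. 0.4, 0.5 or 0.6.
#' @param resolution strip edge length (mm).
#' @inheritParams tissue_state
#' @param tol relative tolerance on the achieved CV.
#' @param D0 initial guess (mm^2/ms).
#' @return list with `D` and `achieved_cv`.
#' @export
calibrate_diffusion <- function(target_cv, resolution = 0.25,
                                remodeling = remodeling_preset("af_remodeled"),
                                tol = 0.02, D0 = NULL) {
  stopifnot(target_cv > 0)
  key <- paste0("cal_", target_cv, "_", resolution, "_",
                paste(format(as.numeric(remodeling), digits = 8),
                      collapse = "_"))
  if (!is.null(.afsim_cache[[key]])) return(.afsim_cache[[key]])
  D <- D0 %||% (.default_D_025 * (target_cv / 0.4)^2 * (resolution / 0.25)^0.5)
  lo <- 0; hi <- Inf; cv <- NA_real_
  best <- NULL
  for (it in 1:20) {
    # below the discrete propagation threshold the wave dies: score CV = 0
    cv <- tryCatch(strip_cv(D, resolution, remodeling)$cv,
                   error = function(e) 0)
    if (is.null(best) || abs(cv - target_cv) < abs(best$achieved_cv - target_cv))
      best <- list(D = D, achieved_cv = cv)
    if (abs(cv - target_cv) / target_cv < tol) break
    if (cv < target_cv) lo <- max(lo, D) else hi <- min(hi, D)
    Dn <- if (cv > 0 && it <= 6) D * (target_cv / cv)^2 else NA
    D <- if (is.finite(Dn) && Dn > lo && Dn < hi) Dn
         else if (is.finite(hi)) (lo + hi) / 2 else D * 2
    if (it == 20)
      stop("diffusion calibration failed to converge in [",
           signif(lo, 3), ", ", signif(hi, 3), "]", call. = FALSE)
  }
  out <- list(D = D, achieved_cv = cv)
  .afsim_cache[[key]] <- out
  out
}
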