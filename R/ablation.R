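# Virtual ablation of high-DF areas: ablated nodes are removed from the
# conduction graph (zero flux with every neighbor, the "non-conduction
# condition") and their ionic dynamics are frozen at rest. Trials branch
# independently from the checkpoint at the end of each DF window.

#' Apply ablation to a diffusion field
#'
#' Marks the masked nodes non-conducting. The input field is unmodified;
#' a new field is returned.
#'
#' @param field a [diffusion_field()].
#' @param mask logical or integer node mask (non-empty).
#' @param n_nodes node count (needed when `field$conduct` is NULL).
#' @return a new `diffusion_field`.
#' @export
apply_ablation <- function(field, mask, n_nodes = NULL) {
  stopifnot(inherits(field, "diffusion_field"))
  if (is.logical(mask)) mask <- which(mask)
  if (!length(mask)) stop("ablation mask is empty", call. = FALSE)
  conduct <- field$conduct %||% rep(TRUE, n_nodes %||%
                                      stop("n_nodes required", call. = FALSE))
  conduct[mask] <- FALSE
  diffusion_field(field$D, conduct, field$Cm)
}

#' Run one virtual-ablation trial
#'
#' Branches from a checkpoint taken at the end of a DF analysis window,
#' ablates the high-DF area of that window's DF map at the given area
#' fraction, and follows the rhythm for `follow_ms`. Outcomes:
#' `AF_terminated` if all activity ceases (event time = last activation),
#' `AT_conversion` if the rhythm organizes (event time = start of the first
#' 2-s stretch in which the probe activation sequences are regular), else
#' `AF_maintained`.
#'
#' @param op the un-ablated `diffusion_operator`.
#' @param checkpoint a `tissue_state` from the end of the DF window.
#' @param df_map the `df_map` of that window.
#' @param fraction ablation extent: 0.10, 0.15 or 0.20 of the conducting
#'   area (any value in (0,1) is accepted).
#' @inheritParams tissue_state
#' @param follow_ms observation period after ablation (ms).
#' @param quiet_ms activity gap declaring termination.
#' @param seed probe seed for the rhythm classifier.
#' @return an `ablation_trial`: mask, outcome label, event time (s).
#' @export
run_ablation_trial <- function(op, checkpoint, df_map, fraction,
                               remodeling = remodeling_preset("af_remodeled"),
                               follow_ms = 30000, quiet_ms = 200, seed = 1) {
  stopifnot(inherits(checkpoint, "tissue_state"))
  mesh <- op$mesh
  mask <- high_df_mask(df_map, mesh$area, fraction)
  field2 <- apply_ablation(op$field, mask, length(op$diag))
  # lesions routinely split the conducting graph; that warning is expected
  op2 <- withCallingHandlers(
    build_diffusion_operator(mesh, field2),
    warning = function(w) {
      if (grepl("disconnected", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  # freeze ablated nodes at rest
  st <- checkpoint$states
  st[, mask] <- as.numeric(resting_state(remodeling))
  state <- structure(list(states = st, t = checkpoint$t,
                          dvdt = replace(checkpoint$dvdt, mask, 0)),
                     class = "tissue_state")
  t0 <- checkpoint$t
  t_end <- t0 + follow_ms
  # run in 1-s segments with early stop; record V over the final 2 s
  final_win <- matrix(c(t_end - 2000, t_end), 1)
  brk <- sort(unique(c(seq(t0, t_end, by = 1000), t_end, t_end - 2000)))
  brk <- brk[brk > t0]
  all_events <- list(); frames_t <- list(); frames_v <- list()
  last_event <- t0
  terminated_at <- NA_real_
  t_prev <- t0
  for (b in brk) {
    rec <- run_simulation(op2, remodeling, duration = b - t_prev,
                          state = state, record_interval = 1,
                          record_windows = final_win)
    state <- attr(rec, "final_state")
    all_events[[length(all_events) + 1]] <- rec$events
    if (length(rec$t)) {
      frames_t[[length(frames_t) + 1]] <- rec$t
      frames_v[[length(frames_v) + 1]] <- rec$V
    }
    if (nrow(rec$events)) last_event <- max(last_event, max(rec$events$time_ms))
    if (b - last_event >= quiet_ms) { terminated_at <- last_event; break }
    t_prev <- b
  }
  events <- do.call(rbind, all_events)
  recording <- structure(list(
    t = if (length(frames_t)) do.call(c, frames_t) else numeric(0),
    V = if (length(frames_v)) do.call(cbind, frames_v) else
      matrix(0, length(op$diag), 0),
    events = events, t0 = t0, t1 = t_end, record_interval = 1,
    n_nodes = length(op$diag), conduct = op2$conduct),
    class = "ap_recording")
  if (!is.na(terminated_at)) {
    outcome <- list(label = "AF_terminated",
                    event_time_s = (terminated_at - t0) / 1000)
  } else {
    lab <- classify_rhythm(recording, c(t_end - 2000, t_end), mesh,
                           seed = seed)
    if (lab$label == "QUIESCENT") {
      outcome <- list(label = "AF_terminated",
                      event_time_s = (last_event - t0) / 1000)
    } else if (lab$label == "AT") {
      outcome <- list(label = "AT_conversion",
                      event_time_s = .first_regular_time(
                        events, lab$probes, t0, t_end) / 1000)
    } else {
      outcome <- list(label = "AF_maintained", event_time_s = NA_real_)
    }
  }
  structure(list(fraction = fraction, mask = mask, outcome = outcome,
                 n_ablated = sum(mask), window = df_map$window,
                 events = events), class = "ablation_trial")
}

# first time (ms after t0) at which >= 90% of probes are regular over a 2-s
# stretch, scanned at 1-s steps from the event record
.first_regular_time <- function(events, probes, t0, t_end) {
  starts <- seq(t0, t_end - 2000, by = 1000)
  for (s in starts) {
    st <- .probe_regularity(events, probes, c(s, s + 2000))
    reg <- mean(st$cov < 10, na.rm = TRUE)
    if (!is.na(reg) && reg >= 0.9) return(s - t0)
  }
  t_end - 2000 - t0
}

#' @export
print.ablation_trial <- function(x, ...) {
  cat("<ablation_trial>", sprintf("%.0f%%", 100 * x$fraction), "ablation,",
      x$n_ablated, "nodes:", x$outcome$label,
      if (!is.na(x$outcome$event_time_s))
        paste0("at ", round(x$outcome$event_time_s, 1), " s") else "", "\n")
  invisible(x)
}

#' Tabulate ablation outcomes (Table-2-style)
#'
#' Accepts either a list of `ablation_trial`s or a counts matrix with one
#' row per ablation fraction and columns `AF_maintained`, `AT_conversion`,
#' `AF_terminated`. Returns counts, percentages and the
#' defragmented-or-terminated rate per fraction.
#'
#' @param x trial list or counts matrix.
#' @return a data frame with one row per fraction.
#' @export
tabulate_outcomes <- function(x) {
  lev <- c("AF_maintained", "AT_conversion", "AF_terminated")
  if (is.matrix(x) || is.data.frame(x)) {
    counts <- as.matrix(x)
    if (is.null(colnames(counts))) colnames(counts) <- lev
    counts <- counts[, lev, drop = FALSE]
    fractions <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  } else {
    if (!length(x)) stop("no trials", call. = FALSE)
    fr <- vapply(x, function(tr) tr$fraction, 0)
    oc <- vapply(x, function(tr) tr$outcome$label, "")
    ufr <- sort(unique(fr))
    counts <- t(vapply(ufr, function(f)
      vapply(lev, function(l) sum(fr == f & oc == l), 0L),
      integer(3)))
    colnames(counts) <- lev
    fractions <- as.character(ufr)
  }
  total <- rowSums(counts)
  if (any(total == 0)) stop("fraction with no trials", call. = FALSE)
  out <- data.frame(fraction = fractions, counts,
                    total = total,
                    pct_maintained = 100 * counts[, 1] / total,
                    pct_at = 100 * counts[, 2] / total,
                    pct_terminated = 100 * counts[, 3] / total,
                    defrag_or_term_rate =
                      100 * (counts[, 2] + counts[, 3]) / total,
                    row.names = NULL, check.names = FALSE)
  out
}
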