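# Dominant-frequency (DF) mapping: per-node power spectra of the membrane
# potential, DF maps per analysis window, high-DF-area masks and regional
# high-DF proportions over the ten LA sections.

#' Analysis window schedule
#'
#' Equal-length, non-overlapping windows T1..Tk. The full-study preset is
#' nine 6-s windows every 30 s.
#'
#' @param n number of windows.
#' @param length_ms window length (ms).
#' @param every_ms window start spacing (ms).
#' @param t0 start of the first window (ms).
#' @return an n x 2 matrix of (start, end) times with rownames T1..Tn.
#' @export
analysis_windows <- function(n = 9, length_ms = 6000, every_ms = 30000,
                             t0 = 0) {
  stopifnot(n >= 1, length_ms > 0, every_ms >= length_ms)
  w <- cbind(start = t0 + (seq_len(n) - 1) * every_ms,
             end = t0 + (seq_len(n) - 1) * every_ms + length_ms)
  rownames(w) <- paste0("T", seq_len(n))
  w
}

#' Periodogram of a voltage trace
#'
#' Mean-removed, Hann-windowed periodogram. The frequency grid spacing is
#' the reciprocal of the trace duration.
#'
#' @param v uniformly sampled signal.
#' @param fs sampling rate (Hz).
#' @return list with `freq` (Hz) and `power`.
#' @export
power_spectrum <- function(v, fs) {
  n <- length(v)
  if (n < 2 * fs) stop("need at least 2 s of data", call. = FALSE)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  x <- (v - mean(v)) * w
  sp <- abs(stats::fft(x))^2 / n
  nf <- floor(n / 2) + 1
  list(freq = (seq_len(nf) - 1) * fs / n, power = sp[seq_len(nf)])
}

#' Dominant frequency of a trace
#'
#' Frequency of the highest periodogram peak within the search band; ties
#' break toward the lower frequency. Silent traces (peak-to-peak amplitude
#' under `silent_mv`) return `NA`, the sentinel for nodes excluded from DF
#' maps.
#'
#' @inheritParams power_spectrum
#' @param band frequency search band (Hz), default 1-20.
#' @param silent_mv amplitude below which a trace is considered silent (mV).
#' @return DF in Hz, or `NA` for a silent trace.
#' @export
dominant_frequency <- function(v, fs, band = c(1, 20), silent_mv = 1) {
  if (band[2] > fs / 2) stop("band exceeds the Nyquist frequency",
                             call. = FALSE)
  if (diff(range(v)) < silent_mv) return(NA_real_)
  ps <- power_spectrum(v, fs)
  sel <- ps$freq >= band[1] & ps$freq <= band[2]
  if (!any(sel)) return(NA_real_)
  fr <- ps$freq[sel]; pw <- ps$power[sel]
  fr[which.max(pw)]   # which.max returns the first (lowest-frequency) tie
}

#' Compute a DF map from a recording window
#'
#' One DF per conducting node from the recorded membrane potential within
#' the window; silent or non-conducting nodes carry the `NA` sentinel.
#'
#' @param recording an `ap_recording` whose V frames cover the window.
#' @param window numeric (start, end) in ms.
#' @param band DF search band (Hz).
#' @return a `df_map`: list with `df` (per node, Hz), `window`,
#'   `resolution` (Hz), `peak_power`.
#' @export
compute_df_map <- function(recording, window, band = c(1, 20)) {
  sel <- recording$t >= window[1] - 1e-9 & recording$t < window[2] - 1e-9
  if (sum(sel) < 3)
    stop("window [", window[1], ", ", window[2],
         ") is not covered by the recording", call. = FALSE)
  fs <- 1000 / recording$record_interval
  if (sum(sel) < 2 * fs) stop("window shorter than 2 s", call. = FALSE)
  X <- recording$V[, sel, drop = FALSE]           # nodes x time
  n <- ncol(X)
  conduct <- recording$conduct %||% rep(TRUE, nrow(X))
  hann <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  Xc <- (X - rowMeans(X)) * rep(hann, each = nrow(X))
  sp <- abs(stats::mvfft(t(Xc)))^2 / n            # freq x nodes
  freq <- (seq_len(n) - 1) * fs / n
  bsel <- freq >= band[1] & freq <= band[2] & freq <= fs / 2
  pw <- sp[bsel, , drop = FALSE]
  idx <- apply(pw, 2, which.max)
  df <- freq[bsel][idx]
  peak <- pw[cbind(idx, seq_along(idx))]
  silent <- apply(X, 1, function(r) diff(range(r))) < 1
  df[silent | !conduct] <- NA_real_
  structure(list(df = df, window = window, resolution = fs / n,
                 peak_power = peak, band = band), class = "df_map")
}

#' High-DF area mask
#'
#' Nodes ranked by DF (descending, ties by node index ascending) are
#' selected greedily until their cumulative lumped area first reaches
#' `fraction` of the total conducting area. Sentinel (silent) nodes are
#' never selected.
#'
#' @param df_map a `df_map`.
#' @param node_areas per-node lumped areas (mm^2).
#' @param fraction target area fraction in (0, 1).
#' @return logical node mask.
#' @export
high_df_mask <- function(df_map, node_areas, fraction = 0.10) {
  stopifnot(fraction > 0, fraction < 1)
  df <- df_map$df
  if (all(is.na(df)))
    stop("all nodes are silent; no high-DF area is defined", call. = FALSE)
  eligible <- which(!is.na(df))
  ord <- eligible[order(-df[eligible], eligible)]
  target <- fraction * sum(node_areas[eligible])
  csum <- cumsum(node_areas[ord])
  k <- which(csum >= target - 1e-12)[1]
  if (is.na(k)) k <- length(ord)
  mask <- logical(length(df))
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Regional proportions of a high-DF mask
#'
#' For each of the ten LA sections: 100 x (masked area in the section) /
#' (section area), the "% High DF Area".
#'
#' @param mask logical node mask (e.g. from [high_df_mask()]).
#' @param mesh a labeled `surface_mesh`.
#' @return named numeric vector R1..R10 (percent).
#' @export
regional_proportions <- function(mask, mesh) {
  if (any(mesh$region == 0))
    stop("mesh is not fully labeled; run partition_regions() first",
         call. = FALSE)
  areas <- mesh_region_areas(mesh)$by_region
  if (any(areas <= 0)) stop("zero-area region", call. = FALSE)
  hit <- vapply(1:10, function(r)
    sum(mesh$area[mask & mesh$region == r]), 0)
  setNames(100 * hit / areas, .region_names)
}

#' @export
print.df_map <- function(x, ...) {
  cat("<df_map> window", x$window[1], "-", x$window[2], "ms,",
      sum(!is.na(x$df)), "of", length(x$df), "nodes,",
      "DF", format(min(x$df, na.rm = TRUE), digits = 3), "-",
      format(max(x$df, na.rm = TRUE), digits = 3), "Hz, resolution",
      format(x$resolution, digits = 3), "Hz\n")
  invisible(x)
}
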