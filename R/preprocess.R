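#' Analysis-segment specification
#'
#' @param phase `"S1_decubitus"` or `"S2_orthostatism"`.
#' @param start Window start in seconds (>= 0).
#' @param duration Window length in seconds (default 300, i.e. 5 min).
#' @return A list of class `segment_spec`.
#' @export
segment_spec <- function(phase = c("S1_decubitus", "S2_orthostatism"),
                         start = 0, duration = 300) {
  phase <- match.arg(phase)
  stopifnot(start >= 0, duration > 0)
  structure(list(phase = phase, start = start, duration = duration),
            class = "segment_spec")
}

#' Detect and correct ectopic/artifact beats
#'
#' A beat is flagged when its interval deviates by more than `dev_threshold`
#' (fractionally) from the running median of `window` surrounding beats.
#' Flagged beats are removed and re-filled by cubic-spline interpolation of
#' the interval tachogram over beat time, preserving beat count; replaced
#' beats are flagged `"interpolated"`.
#'
#' @param rri An [rri_series()] with at least `window` beats.
#' @param dev_threshold Fractional deviation triggering a flag (default 0.3).
#' @param window Running-median window in beats (odd, default 11).
#' @param max_fraction Quality gate: error if more than this fraction of
#'   beats is flagged (default 0.2).
#' @return A list with elements `rri` (corrected series) and `report`
#'   (`n_flagged`, `n_interpolated`, `fraction_edited`).
#' @export
correct_artifacts <- function(rri, dev_threshold = 0.3, window = 11,
                              max_fraction = 0.2) {
  stopifnot(inherits(rri, "rri_series"))
  n <- length(rri$intervals)
  if (n < window)
    stop("correct_artifacts: need at least ", window, " beats, got ", n)
  med <- stats::runmed(rri$intervals, k = window, endrule = "median")
  bad <- abs(rri$intervals - med) / med > dev_threshold
  frac <- mean(bad)
  if (frac > max_fraction)
    stop(sprintf(
      "correct_artifacts: %.1f%% of beats flagged (> %.0f%%); segment should be rejected",
      100 * frac, 100 * max_fraction))
  out <- rri
  if (any(bad)) {
    good_t <- rri$beat_times[!bad]
    good_v <- rri$intervals[!bad]
    sf <- stats::splinefun(good_t, good_v, method = "natural")
    out$intervals[bad] <- sf(rri$beat_times[bad])
    out$flags[bad] <- "interpolated"
    # rebuild beat times so the interval/beat-time invariant holds
    out$beat_times <- rri$beat_times[1L] +
      c(0, cumsum(out$intervals[-1L] / 1000))
    if (any(out$intervals <= 0))
      stop("correct_artifacts: interpolation produced non-positive interval")
  }
  list(rri = rri_series(out$intervals, out$beat_times, out$flags),
       report = list(n_flagged = sum(bad), n_interpolated = sum(bad),
                     fraction_edited = frac))
}

#' Polynomial detrending of a sampled signal
#'
#' Removes the least-squares polynomial fit of the given order, leaving a
#' zero-mean residual.
#'
#' @param x A [sampled_signal()].
#' @param order Polynomial order (>= 0, default 3).
#' @return A [sampled_signal()] of the residuals.
#' @export
detrend_poly <- function(x, order = 3) {
  stopifnot(inherits(x, "sampled_signal"))
  if (order < 0) stop("detrend_poly: order must be >= 0")
  n <- length(x$values)
  if (n <= order + 1) stop("detrend_poly: series too short for order ", order)
  t <- seq_len(n) / x$fs
  fit <- if (order == 0) stats::lm(x$values ~ 1)
         else stats::lm(x$values ~ stats::poly(t, order))
  sampled_signal(as.numeric(stats::residuals(fit)), fs = x$fs,
                 start_time = x$start_time)
}

#' Resample an RR-interval series to a uniform grid
#'
#' Cubic-spline interpolation of the (beat time, interval) tachogram,
#' evaluated on a uniform grid at `fs_out` spanning the first to last beat
#' time. This is the standard step before FFT-based spectral analysis.
#'
#' @param rri An [rri_series()] with at least 4 beats.
#' @param fs_out Output sampling rate in Hz (default 4).
#' @return A [sampled_signal()] in ms.
#' @export
resample_spline <- function(rri, fs_out = 4) {
  stopifnot(inherits(rri, "rri_series"))
  if (length(rri$intervals) < 4) stop("resample_spline: need >= 4 beats")
  t <- rri$beat_times
  grid <- seq(t[1L], t[length(t)], by = 1 / fs_out)
  sf <- stats::splinefun(t, rri$intervals, method = "fmm")
  sampled_signal(sf(grid), fs = fs_out, start_time = t[1L])
}

#' Extract a time window from an RR-interval series
#'
#' Keeps beats whose time falls in the half-open window
#' `[start, start + duration)` and re-offsets beat times to the window start.
#'
#' @param rri An [rri_series()].
#' @param spec A [segment_spec()].
#' @return An [rri_series()] restricted to the window.
#' @export
extract_segment <- function(rri, spec) {
  stopifnot(inherits(rri, "rri_series"), inherits(spec, "segment_spec"))
  t_end <- rri$beat_times[length(rri$beat_times)]
  if (spec$start + spec$duration > t_end + 1e-9)
    stop(sprintf(
      "extract_segment: window [%g, %g) exceeds recording (%.1f s available)",
      spec$start, spec$start + spec$duration, t_end))
  keep <- rri$beat_times >= spec$start &
          rri$beat_times < spec$start + spec$duration
  if (sum(keep) < 2) stop("extract_segment: fewer than 2 beats in window")
  rri_series(rri$intervals[keep],
             beat_times = rri$beat_times[keep] - spec$start,
             flags = rri$flags[keep])
}
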