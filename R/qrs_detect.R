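#' Pan-Tompkins detector configuration
#'
#' Standard constants for the Pan-Tompkins QRS detection chain: band-pass
#' 5-15 Hz (4th-order zero-phase Butterworth), derivative, squaring, 150 ms
#' moving-window integration, adaptive dual thresholds with a 200 ms
#' refractory period.
#'
#' @param bandpass_lo Lower band edge in Hz.
#' @param bandpass_hi Upper band edge in Hz.
#' @param integration_window Moving-window integration length in seconds.
#' @param refractory Minimum inter-beat separation in seconds.
#' @param threshold_decay Fraction controlling how fast the adaptive signal /
#'   noise peak estimates update (exponential running estimate weight).
#' @return A list of class `qrs_config`.
#' @export
qrs_config <- function(bandpass_lo = 5, bandpass_hi = 15,
                       integration_window = 0.150, refractory = 0.200,
                       threshold_decay = 0.125) {
  stopifnot(bandpass_lo > 0, bandpass_hi > bandpass_lo,
            integration_window > 0, refractory > 0,
            threshold_decay > 0, threshold_decay < 1)
  structure(list(bandpass_lo = bandpass_lo, bandpass_hi = bandpass_hi,
                 integration_window = integration_window,
                 refractory = refractory,
                 threshold_decay = threshold_decay),
            class = "qrs_config")
}

#' Detect R-wave peaks in a single-lead ECG
#'
#' Pan-Tompkins chain: zero-phase band-pass, derivative, squaring, moving
#' window integration, then adaptive dual-threshold peak picking with a
#' refractory period. Each trigger from the integrated signal is refined to
#' the argmax of the raw trace within +/-50 ms, so reported peak times are
#' not biased by filter delay.
#'
#' @param ecg A [sampled_signal()] with `fs >= 100` Hz and duration >= 10 s.
#' @param cfg A [qrs_config()].
#' @return Numeric vector of strictly increasing R-peak times in seconds.
#' @export
detect_r_peaks <- function(ecg, cfg = qrs_config()) {
  stopifnot(inherits(ecg, "sampled_signal"))
  fs <- ecg$fs
  x <- ecg$values
  if (fs < 100) stop("detect_r_peaks: sampling rates below 100 Hz unsupported")
  if (length(x) / fs < 10) stop("detect_r_peaks: need at least 10 s of ECG")
  if (stats::sd(x) == 0) stop("detect_r_peaks: flat signal, no beats found")
  if (cfg$bandpass_hi >= fs / 2)
    stop("detect_r_peaks: band-pass upper edge must be below Nyquist")

  bp <- signal::butter(2, c(cfg$bandpass_lo, cfg$bandpass_hi) / (fs / 2),
                       type = "pass")
  xf <- signal::filtfilt(bp, x - mean(x))  # zero-phase -> 4th order effective
  dx <- c(0, diff(xf)) * fs
  sq <- dx^2
  wlen <- max(1L, round(cfg$integration_window * fs))
  integ <- stats::filter(sq, rep(1 / wlen, wlen), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  # local maxima of the integrated signal
  n <- length(integ)
  is_pk <- which(integ[2:(n - 1)] > integ[1:(n - 2)] &
                 integ[2:(n - 1)] >= integ[3:n]) + 1L
  if (length(is_pk) == 0L) stop("detect_r_peaks: no beats found")

  # adaptive dual thresholds (running signal/noise peak estimates)
  decay <- cfg$threshold_decay
  spki <- max(integ[seq_len(min(n, round(2 * fs)))]) * 0.5
  npki <- mean(integ[seq_len(min(n, round(2 * fs)))]) * 0.5
  refr <- cfg$refractory * fs
  trig <- integer(0)
  last <- -Inf
  for (i in is_pk) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] > thr) {
      if ((i - last) > refr) {
        spki <- decay * integ[i] + (1 - decay) * spki
        trig <- c(trig, i)
        last <- i
      } else if (length(trig) && integ[i] > integ[trig[length(trig)]]) {
        # a stronger candidate inside the refractory window supersedes the
        # previous trigger (guards against noise bumps just before a QRS)
        trig[length(trig)] <- i
        last <- i
      } else {
        npki <- decay * integ[i] + (1 - decay) * npki
      }
    } else {
      npki <- decay * integ[i] + (1 - decay) * npki
    }
  }
  if (length(trig) == 0L) stop("detect_r_peaks: no beats found")

  # refine to raw-signal argmax within +/-50 ms of the trigger
  half <- as.integer(round(0.050 * fs))
  peaks <- vapply(trig, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(x), i + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce refractory after refinement
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) > refr)
    while (!all(keep)) {
      peaks <- peaks[keep]
      keep <- c(TRUE, diff(peaks) > refr)
    }
  }
  ecg$start_time + (peaks - 1L) / fs
}

#' Convert an ECG trace to an RR-interval series
#'
#' Runs [detect_r_peaks()] and differences successive peak times.
#'
#' @inheritParams detect_r_peaks
#' @return An [rri_series()] with all beats flagged `"normal"`.
#' @export
ecg_to_rri <- function(ecg, cfg = qrs_config()) {
  pk <- detect_r_peaks(ecg, cfg)
  if (length(pk) < 2L)
    stop("ecg_to_rri: need at least 2 detected peaks")
  rri_series(diff(pk) * 1000, beat_times = pk[-1L])
}
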