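#' Time-domain HRV metrics
#'
#' Classical descriptors of total beat-to-beat variability. Instantaneous
#' heart rate is computed per beat as `60000 / RR_i` (bpm); mean and SD of
#' HR are taken over those per-beat values. SDs are sample SDs (n - 1).
#' NN50 counts successive-interval differences strictly greater than 50 ms.
#'
#' @param rri An [rri_series()] with at least 2 beats.
#' @return Named list: `mean_RR`, `sd_RR` (ms); `mean_HR`, `sd_HR` (bpm);
#'   `RMSSD` (ms); `NN50` (count); `pNN50` (%).
#' @export
time_domain_metrics <- function(rri) {
  stopifnot(inherits(rri, "rri_series"))
  x <- rri$intervals
  n <- length(x)
  if (n < 2) stop("time_domain_metrics: need at least 2 beats")
  hr <- 60000 / x
  d <- diff(x)
  list(mean_RR = mean(x),
       sd_RR = stats::sd(x),
       mean_HR = mean(hr),
       sd_HR = stats::sd(hr),
       RMSSD = sqrt(mean(d^2)),
       NN50 = sum(abs(d) > 50),
       pNN50 = 100 * sum(abs(d) > 50) / (n - 1))
}

#' Spectral band definition
#'
#' Conventional short-term HRV bands. The VLF band is needed for total power
#' and normalized units; 0.003-0.04 Hz is the consensus definition.
#'
#' @param vlf,lf,hf Two-element numeric vectors `(lo, hi)` in Hz.
#' @return List of class `spectral_bands`.
#' @export
spectral_bands <- function(vlf = c(0.003, 0.04), lf = c(0.04, 0.15),
                           hf = c(0.15, 0.40)) {
  stopifnot(vlf[1] < vlf[2], lf[1] < lf[2], hf[1] < hf[2],
            vlf[2] <= lf[1], lf[2] <= hf[1])
  structure(list(vlf = vlf, lf = lf, hf = hf), class = "spectral_bands")
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram. Segments of `window_s` seconds with
#' `overlap` fractional overlap; each segment is mean-removed before
#' windowing. The one-sided density is scaled so that its trapezoidal
#' integral over (0, fs/2] matches the input variance (Parseval).
#'
#' @param x A [sampled_signal()], uniformly sampled, duration >= 60 s.
#' @param window_s Segment length in seconds (default 256; capped at the
#'   signal duration).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd` (ms^2/Hz), class `hrv_spectrum`.
#' @export
welch_psd <- function(x, window_s = 256, overlap = 0.5) {
  stopifnot(inherits(x, "sampled_signal"))
  fs <- x$fs
  v <- x$values
  n <- length(v)
  if (n / fs < 60) stop("welch_psd: need at least 60 s of signal")
  L <- min(n, round(window_s * fs))
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))  # Hann
  scale <- fs * sum(w^2)
  acc <- numeric(floor(L / 2) + 1L)
  for (s in starts) {
    seg <- v[s:(s + L - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    pxx <- Mod(X[seq_along(acc)])^2 / scale
    acc <- acc + pxx
  }
  pxx <- acc / length(starts)
  # one-sided: double all bins except DC (and Nyquist when L even)
  dbl <- rep(2, length(pxx)); dbl[1] <- 1
  if (L %% 2 == 0) dbl[length(pxx)] <- 1
  pxx <- pxx * dbl
  freq <- (seq_along(pxx) - 1L) * fs / L
  # variance-preserving normalisation: windowing and finite segmentation
  # bias the raw integral by a few percent; rescale so the trapezoidal
  # integral over (0, fs/2] equals the variance of the input exactly
  integ <- sum(diff(freq) * (pxx[-1] + pxx[-length(pxx)]) / 2)
  v0 <- stats::var(v)
  if (integ > 0 && v0 > 0) pxx <- pxx * v0 / integ
  structure(list(freq = freq, psd = pxx), class = "hrv_spectrum")
}

# Trapezoidal integral of the PSD over [lo, hi], with linear interpolation
# at the band edges.
band_power <- function(spec, lo, hi) {
  f <- spec$freq; p <- spec$psd
  if (hi <= f[1] || lo >= f[length(f)]) return(0)
  inside <- f > lo & f < hi
  fk <- f[inside]; pk <- p[inside]
  pe_lo <- stats::approx(f, p, xout = max(lo, f[1]))$y
  pe_hi <- stats::approx(f, p, xout = min(hi, f[length(f)]))$y
  fk <- c(max(lo, f[1]), fk, min(hi, f[length(f)]))
  pk <- c(pe_lo, pk, pe_hi)
  sum(diff(fk) * (pk[-1] + pk[-length(pk)]) / 2)
}

#' Frequency-domain HRV metrics from a spectrum
#'
#' Band powers by trapezoidal integration of the PSD; peaks as the frequency
#' of maximum density within each band (spectral centroid available via
#' `peak_mode = "centroid"`). Total power is VLF + LF + HF; percentages are
#' relative to total power; normalized units relative to `(total - VLF)`.
#'
#' @param spec A spectrum from [welch_psd()].
#' @param bands A [spectral_bands()].
#' @param peak_mode `"argmax"` (default) or `"centroid"`.
#' @return Named list of 10 metrics: `LF_peak`, `HF_peak` (Hz); `LF_power`,
#'   `HF_power`, `tot_power` (ms^2); `LF_power_prc`, `HF_power_prc` (%);
#'   `LF_power_nu`, `HF_power_nu` (n.u.); `LF_HF_power` (ratio).
#' @export
band_metrics <- function(spec, bands = spectral_bands(),
                         peak_mode = c("argmax", "centroid")) {
  peak_mode <- match.arg(peak_mode)
  stopifnot(inherits(spec, "hrv_spectrum"))
  if (max(spec$freq) < bands$hf[2])
    stop("band_metrics: spectrum does not cover the HF band")
  vlf <- band_power(spec, bands$vlf[1], bands$vlf[2])
  lf <- band_power(spec, bands$lf[1], bands$lf[2])
  hf <- band_power(spec, bands$hf[1], bands$hf[2])
  tot <- vlf + lf + hf
  pk <- function(b) {
    sel <- spec$freq >= b[1] & spec$freq <= b[2]
    f <- spec$freq[sel]; p <- spec$psd[sel]
    if (!length(f) || all(p == 0)) return(NA_real_)
    if (peak_mode == "argmax") f[which.max(p)] else sum(f * p) / sum(p)
  }
  ratio <- if (hf == 0) {
    warning("band_metrics: HF power is zero; LF/HF reported as Inf")
    Inf
  } else lf / hf
  denom_nu <- tot - vlf
  list(LF_peak = pk(bands$lf),
       HF_peak = pk(bands$hf),
       LF_power = lf,
       LF_power_prc = if (tot > 0) 100 * lf / tot else NA_real_,
       LF_power_nu = if (denom_nu > 0) 100 * lf / denom_nu else NA_real_,
       HF_power = hf,
       HF_power_prc = if (tot > 0) 100 * hf / tot else NA_real_,
       HF_power_nu = if (denom_nu > 0) 100 * hf / denom_nu else NA_real_,
       LF_HF_power = ratio,
       tot_power = tot)
}

#' Frequency-domain HRV metrics for an RR segment
#'
#' Convenience chain: cubic-spline resampling to `fs_out`, polynomial
#' detrending, Welch PSD, band metrics.
#'
#' @param rri An [rri_series()].
#' @param fs_out Resampling rate in Hz (default 4).
#' @param detrend_order Polynomial detrending order (default 3).
#' @param bands A [spectral_bands()].
#' @return As [band_metrics()].
#' @export
freq_domain_metrics <- function(rri, fs_out = 4, detrend_order = 3,
                                bands = spectral_bands()) {
  x <- resample_spline(rri, fs_out = fs_out)
  x <- detrend_poly(x, order = detrend_order)
  band_metrics(welch_psd(x), bands = bands)
}
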