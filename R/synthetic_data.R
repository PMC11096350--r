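# Synthetic-data generation.
#
# An integral pulse frequency modulation (IPFM) model drives beat emission:
# beats occur when the running integral of a modulated rate m(t)/Tbar
# crosses successive integers. LF/HF sinusoidal modulation maps directly to
# the spectral metrics; a 1/f^beta noise term moves the fractal/complexity
# metrics (DFA alpha, CorDim) smoothly between presets.

#' IPFM generator parameters
#'
#' @param target_HR Mean heart rate in bpm (30-200).
#' @param a_LF,a_HF Fractional amplitudes of the LF and HF sinusoidal
#'   modulation of the instantaneous rate.
#' @param f_LF,f_HF Modulation frequencies in Hz (defaults 0.095 / 0.25).
#' @param noise_sd Fractional SD of the 1/f^beta modulation noise.
#' @param noise_beta Spectral exponent beta of the noise (0 = white,
#'   2 = Brownian-like; default 1).
#' @param duration Recording length in seconds (default 300).
#' @return List of class `generator_params`.
#' @export
generator_params <- function(target_HR = 70, a_LF = 0.03, a_HF = 0.03,
                             f_LF = 0.095, f_HF = 0.25,
                             noise_sd = 0.02, noise_beta = 1,
                             duration = 300) {
  stopifnot(target_HR >= 30, target_HR <= 200,
            a_LF >= 0, a_HF >= 0, noise_sd >= 0,
            noise_beta >= 0, noise_beta <= 2, duration > 0)
  if (a_LF + a_HF + 3 * noise_sd >= 1)
    stop("generator_params: a_LF + a_HF + 3*noise_sd must be < 1 ",
         "(interval positivity)")
  structure(list(target_HR = target_HR, a_LF = a_LF, a_HF = a_HF,
                 f_LF = f_LF, f_HF = f_HF, noise_sd = noise_sd,
                 noise_beta = noise_beta, duration = duration),
            class = "generator_params")
}

# Band-limited 1/f^beta noise: white Gaussian spectrum shaped by f^(-beta/2)
# on a 4 Hz grid, standardized to unit SD, cubic-interpolated to `times`.
powerlaw_noise <- function(times, beta, fs = 4) {
  t_max <- max(times)
  n <- max(8L, ceiling(t_max * fs) + 2L)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1e-12, seq_len(n - 1)) * fs / n  # avoid DC blow-up
  f <- pmin(f, fs - f + 1e-12)            # two-sided symmetric shaping
  W <- W * f^(-beta / 2)
  W[1] <- 0
  z <- Re(stats::fft(W, inverse = TRUE)) / n
  z <- (z - mean(z)) / stats::sd(z)
  grid_t <- (seq_len(n) - 1) / fs
  stats::splinefun(grid_t, z, method = "fmm")(times)
}

#' Generate an RR-interval series with the IPFM model
#'
#' The modulation is
#' `m(t) = 1 + a_LF sin(2 pi f_LF t + phi1) + a_HF sin(2 pi f_HF t + phi2)
#'  + noise_sd * z_beta(t)`, and a beat is emitted each time
#' `integral of m(t) / Tbar` crosses an integer, with `Tbar = 60/target_HR`.
#' Phases are drawn uniformly; seed the R RNG beforehand for reproducible
#' series.
#'
#' @param params A [generator_params()].
#' @return An [rri_series()].
#' @export
ipfm_generate <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  dt <- 0.01
  tt <- seq(0, p$duration + 2, by = dt)
  phi <- stats::runif(2, 0, 2 * pi)
  m <- 1 + p$a_LF * sin(2 * pi * p$f_LF * tt + phi[1]) +
           p$a_HF * sin(2 * pi * p$f_HF * tt + phi[2])
  if (p$noise_sd > 0) m <- m + p$noise_sd * powerlaw_noise(tt, p$noise_beta)
  if (any(m <= 0))
    stop("ipfm_generate: modulation dips below zero; reduce amplitudes/noise")
  tbar <- 60 / p$target_HR
  theta <- cumsum(m) * dt / tbar          # running integral of m/Tbar
  kmax <- floor(theta[length(theta)])
  if (kmax < 2) stop("ipfm_generate: duration too short to emit beats")
  # invert theta(t) at integer crossings by linear interpolation
  beat_t <- stats::approx(theta, tt, xout = seq_len(kmax))$y
  beat_t <- beat_t[beat_t <= p$duration]
  intervals <- diff(beat_t) * 1000
  rri_series(intervals, beat_times = beat_t[-1L])
}

#' Table-like two-group, two-position cohort preset
#'
#' Generator parameter cells for the diffuse (dcSSc) and limited (lcSSc)
#' clinical forms in decubitus (S1) and orthostatism (S2). The defaults
#' encode the study conditions: higher heart rate and lower variability in
#' the diffuse group, a larger orthostatic HR rise in the diffuse group
#' (+14 vs +9 bpm), and opposite-signed stand-up responses of long-term
#' variability and complexity (diffuse: variability and correlation
#' dimension fall on standing, via smaller modulation amplitudes and a
#' steeper noise exponent; limited: both rise slightly).
#'
#' @param n_dc,n_lc Group sizes (defaults 16 and 42).
#' @return List of class `cohort_preset` with elements `cells` (named list
#'   `dcSSc_S1`, `dcSSc_S2`, `lcSSc_S1`, `lcSSc_S2`) and `n` (named sizes).
#' @export
cohort_preset <- function(n_dc = 16, n_lc = 42) {
  stopifnot(n_dc >= 1, n_lc >= 1)
  cells <- list(
    dcSSc_S1 = generator_params(target_HR = 74, a_LF = 0.040, a_HF = 0.035,
                                noise_sd = 0.025, noise_beta = 1.0),
    dcSSc_S2 = generator_params(target_HR = 88, a_LF = 0.030, a_HF = 0.012,
                                noise_sd = 0.015, noise_beta = 1.5),
    lcSSc_S1 = generator_params(target_HR = 68, a_LF = 0.032, a_HF = 0.028,
                                noise_sd = 0.020, noise_beta = 1.0),
    lcSSc_S2 = generator_params(target_HR = 77, a_LF = 0.048, a_HF = 0.018,
                                noise_sd = 0.026, noise_beta = 0.9))
  structure(list(cells = cells, n = c(dcSSc = n_dc, lcSSc = n_lc)),
            class = "cohort_preset")
}

# Subject-level jitter of a parameter cell: multiplicative log-normal
# factors shared across positions (passed in), small position-specific
# jitter added here.
jitter_params <- function(cell, subj_fac) {
  generator_params(
    target_HR = min(200, max(30, cell$target_HR * subj_fac$hr *
                               exp(stats::rnorm(1, 0, 0.03)))),
    a_LF = cell$a_LF * subj_fac$amp * exp(stats::rnorm(1, 0, 0.10)),
    a_HF = cell$a_HF * subj_fac$amp * exp(stats::rnorm(1, 0, 0.10)),
    f_LF = cell$f_LF, f_HF = cell$f_HF,
    noise_sd = cell$noise_sd * subj_fac$amp * exp(stats::rnorm(1, 0, 0.10)),
    noise_beta = min(2, max(0, cell$noise_beta + subj_fac$beta)),
    duration = cell$duration)
}

#' Generate a synthetic two-group cohort on disk
#'
#' Draws per-subject parameters (log-normal jitter around the preset cell
#' means, with subject-level factors shared between the two positions so the
#' design is genuinely paired), generates both 5-min segments with the IPFM
#' model, writes the RR files and a manifest CSV, and returns the
#' ground-truth parameter table for recovery tests.
#'
#' @param preset A [cohort_preset()].
#' @param seed Integer RNG seed.
#' @param dir Output directory (created if needed).
#' @return List with `manifest` (a `cohort_manifest` data.frame), `dir`, and
#'   `truth` (per subject x position generator parameters).
#' @export
make_cohort <- function(preset = cohort_preset(), seed = 1,
                        dir = tempfile("cohort")) {
  stopifnot(inherits(preset, "cohort_preset"))
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truth <- list()
  sid <- 0L
  for (grp in names(preset$n)) {
    for (k in seq_len(preset$n[[grp]])) {
      sid <- sid + 1L
      id <- sprintf("subj%03d", sid)
      subj_fac <- list(hr = exp(stats::rnorm(1, 0, 0.11)),
                       amp = exp(stats::rnorm(1, 0, 0.30)),
                       beta = stats::rnorm(1, 0, 0.12))
      paths <- character(2)
      for (pos in c("S1", "S2")) {
        cell <- preset$cells[[paste(grp, pos, sep = "_")]]
        pars <- jitter_params(cell, subj_fac)
        rri <- ipfm_generate(pars)
        path <- file.path(dir, paste0(id, "_", pos, ".rri"))
        write_rri(rri, path)
        paths[if (pos == "S1") 1 else 2] <- path
        truth[[length(truth) + 1L]] <-
          data.frame(subject_id = id, group = grp, position = pos,
                     target_HR = pars$target_HR, a_LF = pars$a_LF,
                     a_HF = pars$a_HF, noise_sd = pars$noise_sd,
                     noise_beta = pars$noise_beta)
      }
      rows[[sid]] <- data.frame(subject_id = id, group = grp,
                                path_S1 = paths[1], path_S2 = paths[2],
                                input_kind = "rri")
    }
  }
  manifest <- do.call(rbind, rows)
  class(manifest) <- c("cohort_manifest", "data.frame")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  list(manifest = manifest, dir = dir, truth = do.call(rbind, truth))
}

#' Render a synthetic single-lead ECG from an RR series
#'
#' Places a biphasic 80 ms QRS template at each beat time, adds 0.3 Hz
#' baseline wander and white Gaussian noise at the requested SNR. Ground
#' truth beat times are attached as attribute `beat_times`.
#'
#' @param rri An [rri_series()].
#' @param fs Sampling rate in Hz (>= 100; default 1000).
#' @param snr_db Signal-to-noise ratio in dB (`Inf` = noise free).
#' @return A [sampled_signal()] with attribute `beat_times`.
#' @export
synth_ecg <- function(rri, fs = 1000, snr_db = Inf) {
  stopifnot(inherits(rri, "rri_series"))
  if (fs < 100) stop("synth_ecg: sampling rates below 100 Hz unsupported")
  t0 <- rri$beat_times[1L] - rri$intervals[1L] / 1000
  beats <- c(t0, rri$beat_times)
  dur <- max(beats) + 0.5
  n <- ceiling(dur * fs)
  x <- numeric(n)
  # biphasic QRS template: sharp R peak with Q/S undershoots, 80 ms support
  tt <- seq(-0.04, 0.04, by = 1 / fs)
  tmpl <- exp(-(tt / 0.008)^2) - 0.25 * exp(-((tt - 0.018) / 0.010)^2) -
          0.15 * exp(-((tt + 0.018) / 0.010)^2)
  off <- which.max(tmpl) - 1L
  for (b in beats) {
    i0 <- round(b * fs) + 1L - off
    idx <- seq_along(tmpl) + i0 - 1L
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + tmpl[ok]
  }
  tgrid <- (seq_len(n) - 1) / fs
  x <- x + 0.10 * sin(2 * pi * 0.3 * tgrid)
  if (is.finite(snr_db)) {
    noise_sd <- sqrt(mean(x^2) / 10^(snr_db / 10))
    x <- x + stats::rnorm(n, 0, noise_sd)
  }
  out <- sampled_signal(x, fs = fs, start_time = 0)
  attr(out, "beat_times") <- beats
  out
}

#' Inject simulated ectopic beats
#'
#' Splits selected beats into a premature beat (40% of the original
#' interval) followed by the compensatory remainder, mimicking an ectopic
#' plus compensatory pause. Selected positions are kept at least 3 beats
#' apart.
#'
#' @param rri An [rri_series()].
#' @param rate Injections per 100 beats (>= 0).
#' @param seed Integer RNG seed.
#' @return List with `rri` (modified series) and `positions` (indices of the
#'   premature beats in the modified series).
#' @export
inject_ectopic <- function(rri, rate, seed = 1) {
  stopifnot(inherits(rri, "rri_series"), rate >= 0)
  n <- length(rri$intervals)
  n_inj <- round(rate / 100 * n)
  if (n_inj == 0) return(list(rri = rri, positions = integer(0)))
  if (n_inj * 3 > n - 4)
    stop("inject_ectopic: rate too high; injection windows overlap")
  set.seed(seed)
  cand <- 3:(n - 2)
  pos <- sort(sample(cand, n_inj))
  while (any(diff(pos) < 3)) {
    pos <- sort(sample(cand, n_inj))
  }
  ints <- as.list(rri$intervals)
  for (p in rev(pos)) {
    iv <- ints[[p]]
    ints[[p]] <- c(0.4 * iv, 0.6 * iv)
  }
  ints <- unlist(ints)
  out_pos <- pos + seq_along(pos) - 1L  # index shift from earlier splits
  t0 <- rri$beat_times[1L] - rri$intervals[1L] / 1000
  bt <- t0 + cumsum(ints) / 1000
  list(rri = rri_series(ints, beat_times = bt), positions = out_pos)
}
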