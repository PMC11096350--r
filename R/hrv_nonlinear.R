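# Nonlinear-domain HRV metrics.
#
# All operations work on the corrected beat-to-beat interval series (ms),
# not on the resampled tachogram: nonlinear structure lives in the beat
# ordering itself.

#' Time-delay embedding of a numeric series
#'
#' Builds the matrix of delay vectors
#' `X_i = (x_i, x_{i+tau}, ..., x_{i+(m-1)tau})`.
#'
#' @param x Numeric vector.
#' @param m Embedding dimension (>= 1).
#' @param tau Lag in samples (>= 1).
#' @return A numeric matrix with one delay vector per row.
#' @export
embed_delay <- function(x, m, tau = 1) {
  stopifnot(m >= 1, tau >= 1)
  n <- length(x)
  M <- n - (m - 1) * tau
  if (M < 2) stop("embed_delay: series too short for m = ", m,
                  ", tau = ", tau)
  idx <- outer(seq_len(M), (seq_len(m) - 1L) * tau, `+`)
  matrix(x[idx], nrow = M, ncol = m)
}

#' Poincare plot geometry
#'
#' Dispersions of the lag-1 return map `RR(n+1)` vs `RR(n)`. SD1 (minor
#' axis) captures beat-to-beat variability, SD2 (major axis) long-term
#' variability:
#' `SD1^2 = mean(dRR^2)/2`, `SD2^2 = 2*var_p(RR) - mean(dRR^2)/2`,
#' where `dRR` are successive differences and `var_p` the population
#' variance. The uncentered second moment of `dRR` is used so that the
#' classical identity `SD1 = RMSSD / sqrt(2)` holds exactly.
#'
#' @param rri An [rri_series()] with >= 3 beats.
#' @return Named list `SD1`, `SD2` (ms) and `SD1_SD2` (ratio; `NaN` for a
#'   constant series).
#' @export
poincare <- function(rri) {
  stopifnot(inherits(rri, "rri_series"))
  x <- rri$intervals
  if (length(x) < 3) stop("poincare: need at least 3 beats")
  d <- diff(x)
  sd1sq <- mean(d^2) / 2
  varp <- mean((x - mean(x))^2)
  sd2sq <- max(0, 2 * varp - sd1sq)
  sd1 <- sqrt(sd1sq); sd2 <- sqrt(sd2sq)
  list(SD1 = sd1, SD2 = sd2,
       SD1_SD2 = if (sd2 == 0) NaN else sd1 / sd2)
}

#' Recurrence quantification analysis
#'
#' Embeds the interval series (dimension `m`, lag `tau`), thresholds the
#' pairwise distance matrix at `r`, and quantifies the diagonal-line
#' structure of the recurrence matrix. The line of identity is excluded
#' everywhere; lines are counted on the upper triangle (the matrix is
#' symmetric). Defaults follow the convention `r = sqrt(m) * SD` of the
#' interval series.
#'
#' @param rri An [rri_series()].
#' @param m Embedding dimension (default 10).
#' @param tau Lag in beats (default 1).
#' @param r Recurrence threshold; default `sqrt(m) * sd(intervals)`.
#' @param lmin Minimum counted diagonal-line length in beats (default 2).
#' @param norm Distance norm, `"euclidean"` (default) or `"chebyshev"`.
#' @param theiler Additional Theiler exclusion around the line of identity
#'   (default 0: all off-diagonal pairs are eligible).
#' @return Named list: `Lmin`, `Lmean`, `Lmax` (beats), `DIV` (1/`Lmax`),
#'   `REC`, `DET` (%), `ShanEn` (nats, Shannon entropy of the counted
#'   line-length histogram). All-`NaN` with a warning when no point recurs.
#' @export
rqa <- function(rri, m = 10, tau = 1, r = NULL, lmin = 2,
                norm = c("euclidean", "chebyshev"), theiler = 0) {
  norm <- match.arg(norm)
  x <- if (inherits(rri, "rri_series")) rri$intervals else as.numeric(rri)
  if (length(x) <= (m - 1) * tau + lmin)
    stop("rqa: series too short for embedding (m = ", m, ", tau = ", tau, ")")
  if (is.null(r)) r <- sqrt(m) * stats::sd(x)
  if (!is.finite(r) || r <= 0) stop("rqa: threshold r must be positive")
  X <- embed_delay(x, m, tau)
  M <- nrow(X)
  R <- dist_mat(X, norm) <= r
  diag(R) <- FALSE
  if (theiler > 0) {
    for (k in seq_len(min(theiler, M - 1L))) {
      R[cbind(seq_len(M - k), seq_len(M - k) + k)] <- FALSE
      R[cbind(seq_len(M - k) + k, seq_len(M - k))] <- FALSE
    }
  }
  n_rec_upper <- sum(R[upper.tri(R)])
  rec_pct <- 100 * 2 * n_rec_upper / (M * (M - 1))
  if (n_rec_upper == 0L) {
    warning("rqa: no recurrent points; metrics undefined")
    return(list(Lmin = NaN, Lmean = NaN, Lmax = NaN, DIV = NaN,
                REC = 0, DET = NaN, ShanEn = NaN))
  }
  # diagonal line lengths on the upper triangle, offsets 1..M-1
  lens <- integer(0)
  pts_on_lines <- 0L
  for (k in seq.int(max(1L, theiler + 1L), M - 1L)) {
    dvec <- R[cbind(seq_len(M - k), seq_len(M - k) + k)]
    rl <- rle(dvec)
    ll <- rl$lengths[rl$values]
    ll <- ll[ll >= lmin]
    if (length(ll)) {
      lens <- c(lens, ll)
      pts_on_lines <- pts_on_lines + sum(ll)
    }
  }
  if (length(lens) == 0L) {
    return(list(Lmin = NaN, Lmean = NaN, Lmax = NaN, DIV = NaN,
                REC = rec_pct, DET = 0, ShanEn = NaN))
  }
  p <- tabulate(lens)
  p <- p[p > 0] / length(lens)
  list(Lmin = min(lens),
       Lmean = mean(lens),
       Lmax = max(lens),
       DIV = 1 / max(lens),
       REC = rec_pct,
       DET = 100 * pts_on_lines / n_rec_upper,
       ShanEn = -sum(p * log(p)))
}

# Full pairwise distance matrix for small/medium point sets.
dist_mat <- function(X, norm = "euclidean") {
  if (norm == "euclidean") {
    as.matrix(stats::dist(X))
  } else {
    M <- nrow(X)
    D <- matrix(0, M, M)
    for (j in seq_len(ncol(X))) {
      D <- pmax(D, abs(outer(X[, j], X[, j], `-`)))
    }
    D
  }
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centered series, splits it into non-overlapping boxes
#' of each size `n`, removes a per-box linear trend, and regresses
#' `log F(n)` on `log n`. `alpha1` uses the short-range box sizes, `alpha2`
#' the long-range ones (integer box sizes within the inclusive ranges).
#'
#' @param rri An [rri_series()] or numeric vector; >= 130 beats.
#' @param short Integer box-size range for `alpha1` (default 4-16).
#' @param long Integer box-size range for `alpha2` (default 16-64).
#' @return Named list `alpha1`, `alpha2`.
#' @export
dfa <- function(rri, short = c(4, 16), long = c(16, 64)) {
  x <- if (inherits(rri, "rri_series")) rri$intervals else as.numeric(rri)
  nmax <- max(long)
  if (length(x) < 2 * nmax)
    stop("dfa: need at least ", 2 * nmax, " beats")
  if (stats::sd(x) == 0)
    stop("dfa: constant series has undefined scaling exponent")
  y <- cumsum(x - mean(x))
  N <- length(y)
  sizes <- seq.int(min(short), max(long))
  Fn <- vapply(sizes, function(n) {
    nbox <- N %/% n
    ym <- matrix(y[seq_len(nbox * n)], nrow = n)
    t <- seq_len(n)
    res <- stats::lm.fit(cbind(1, t), ym)$residuals
    sqrt(mean(res^2))
  }, numeric(1))
  slope_over <- function(rng) {
    sel <- sizes >= rng[1] & sizes <= rng[2]
    stats::coef(stats::lm(log(Fn[sel]) ~ log(sizes[sel])))[[2]]
  }
  list(alpha1 = slope_over(short), alpha2 = slope_over(long))
}

# Shared template-match counting for the entropies (Chebyshev distance).
# Returns, for each of the first `n_templates` delay vectors of length m,
# the number of other template vectors within r (self-match included).
template_counts <- function(x, m, r, n_templates) {
  X <- embed_delay(x, m, 1L)[seq_len(n_templates), , drop = FALSE]
  D <- dist_mat(X, "chebyshev")
  rowSums(D <= r)
}

#' Approximate entropy
#'
#' `ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r)` with self-matches included,
#' Chebyshev distance, and `r` defaulting to `0.2 * sd` of the series.
#'
#' @param rri An [rri_series()] or numeric vector.
#' @param m Template length (default 2).
#' @param r Tolerance; default `0.2 * sd(intervals)`.
#' @return ApEn in nats.
#' @export
apen <- function(rri, m = 2, r = NULL) {
  x <- if (inherits(rri, "rri_series")) rri$intervals else as.numeric(rri)
  N <- length(x)
  if (N < m + 2) stop("apen: need at least m + 2 beats")
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  if (!is.finite(r) || r <= 0) stop("apen: tolerance r must be positive")
  phi <- function(mm) {
    cnt <- template_counts(x, mm, r, N - mm + 1L)
    mean(log(cnt / (N - mm + 1L)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` and `A` count template pairs
#' (self-matches excluded, Chebyshev distance) of length `m` and `m + 1`,
#' both over the first `N - m` delay vectors.
#'
#' @inheritParams apen
#' @return SampEn in nats; `NaN` with a warning when no pair matches.
#' @export
sampen <- function(rri, m = 2, r = NULL) {
  x <- if (inherits(rri, "rri_series")) rri$intervals else as.numeric(rri)
  N <- length(x)
  if (N < m + 2) stop("sampen: need at least m + 2 beats")
  if (is.null(r)) r <- 0.2 * stats::sd(x)
  if (!is.finite(r) || r <= 0) stop("sampen: tolerance r must be positive")
  nt <- N - m
  B <- (sum(template_counts(x, m, r, nt)) - nt) / 2
  A <- (sum(template_counts(x, m + 1L, r, nt)) - nt) / 2
  if (B == 0 || A == 0) {
    warning("sampen: no matching template pairs; SampEn undefined")
    return(NaN)
  }
  -log(A / B)
}

#' Correlation sum of an embedded series
#'
#' Fraction of distinct embedded point pairs closer than `r`:
#' `C(r) = 2 / (M (M - 1)) * sum_{i<j} H(r - ||X_i - X_j||)`,
#' where `H` is the Heaviside step (`H(0) = 1`, i.e. distances exactly equal
#' to `r` count). An `i < j` sum with a `1 / (N (N - 1))` prefactor yields
#' exactly half this value; the constant factor does not affect log-log
#' slopes, and the fraction-of-pairs convention is used here so that
#' `C -> 1` as `r -> Inf`.
#'
#' @param rri An [rri_series()] or numeric vector.
#' @param m Embedding dimension.
#' @param tau Lag (default 1).
#' @param r Radius, a positive scalar or vector.
#' @param norm Distance norm (default `"euclidean"`).
#' @return Numeric vector of `C` values, one per element of `r`.
#' @export
correlation_sum <- function(rri, m, tau = 1, r,
                            norm = c("euclidean", "chebyshev")) {
  norm <- match.arg(norm)
  x <- if (inherits(rri, "rri_series")) rri$intervals else as.numeric(rri)
  if (any(!is.finite(r)) || any(r <= 0))
    stop("correlation_sum: r must be positive")
  X <- embed_delay(x, m, tau)
  M <- nrow(X)
  D <- dist_mat(X, norm)
  d <- D[upper.tri(D)]
  vapply(r, function(rr) mean(d <= rr), numeric(1))
}

#' Grassberger-Procaccia correlation dimension
#'
#' Estimates the small-radius slope of `log C(r)` vs `log r`. The
#' correlation sum is evaluated on a 30-point geometric radius grid
#' spanning `[0.025, 1] * sqrt(m) * sd` of the series (the natural distance
#' scale of the m-dimensional embedding), and the dimension is the
#' least-squares slope over the 5 grid points centred nearest `r_center`
#' (default 15% of the series SD). A one-point `r -> 0` limit is undefined
#' on finite data, and at 5-min segment lengths the correlation sum is
#' often zero at the nominal centre; the slope window then slides to the
#' smallest radii whose `C` is statistically resolvable (at least
#' `min_pairs` recurrent pairs and `C < 1`), which is the closest
#' realizable approach to the small-radius limit. The result is clipped to
#' `[0, m]`.
#'
#' @param rri An [rri_series()] or numeric vector with >= 100 beats.
#' @param m Embedding dimension (default 10).
#' @param tau Lag (default 1).
#' @param r_center Radius (ms) at which the local slope is read; default
#'   `0.15 * sd(intervals)`.
#' @param n_grid Number of radius grid points (default 30).
#' @param half_window Grid points on each side of the centre used in the
#'   slope fit (default 2, i.e. a 5-point window).
#' @param min_pairs Minimum recurrent pair count for a grid point to enter
#'   the slope fit (default 5).
#' @return Correlation dimension (dimensionless); `NaN` with a warning when
#'   fewer than 3 usable grid points exist anywhere on the grid.
#' @export
cordim <- function(rri, m = 10, tau = 1, r_center = NULL, n_grid = 30,
                   half_window = 2, min_pairs = 5) {
  x <- if (inherits(rri, "rri_series")) rri$intervals else as.numeric(rri)
  if (length(x) < 100) stop("cordim: need at least 100 beats")
  s <- stats::sd(x)
  if (s == 0) return(0)  # all embedded points identical: C(r) = 1, slope 0
  if (is.null(r_center)) r_center <- 0.15 * s
  scale <- sqrt(m) * s
  rs <- exp(seq(log(0.025), log(1), length.out = n_grid)) * scale
  C <- correlation_sum(x, m = m, tau = tau, r = rs)
  M <- length(x) - (m - 1) * tau
  npairs <- M * (M - 1) / 2
  usable <- which(C * npairs >= min_pairs & C < 1)
  if (length(usable) < 3) {
    warning("cordim: too few usable radii; dimension undefined")
    return(NaN)
  }
  ctr <- which.min(abs(log(rs) - log(r_center)))
  win <- intersect(seq.int(ctr - half_window, ctr + half_window), usable)
  if (length(win) < 3)
    win <- usable[seq_len(min(2 * half_window + 1, length(usable)))]
  slope <- stats::coef(stats::lm(log(C[win]) ~ log(rs[win])))[[2]]
  min(max(slope, 0), m)
}

#' All nonlinear-domain metrics for one segment
#'
#' Convenience wrapper running [poincare()], [rqa()], [dfa()], [apen()],
#' [sampen()] and [cordim()] with their field-standard defaults.
#'
#' @param rri An [rri_series()].
#' @return Named list of the nonlinear metric set.
#' @export
nonlinear_metrics <- function(rri) {
  pc <- poincare(rri)
  rq <- rqa(rri)
  df <- dfa(rri)
  c(pc,
    list(ApEn = apen(rri), SampEn = sampen(rri)),
    df,
    list(CorDim = cordim(rri)),
    rq)
}
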