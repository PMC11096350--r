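# Independent brute-force reference implementations used as oracles.
# These deliberately use naive double loops and materialized matrices,
# sharing no code with the package internals.

oracle_embed <- function(x, m, tau) {
  M <- length(x) - (m - 1) * tau
  out <- matrix(NA_real_, M, m)
  for (i in seq_len(M))
    for (k in seq_len(m))
      out[i, k] <- x[i + (k - 1) * tau]
  out
}

oracle_dist <- function(a, b, norm) {
  if (norm == "euclidean") sqrt(sum((a - b)^2)) else max(abs(a - b))
}

# Full RQA by explicit matrix construction and per-diagonal run scanning
# (upper triangle, line of identity excluded).
oracle_rqa <- function(x, m, tau, r, lmin = 2) {
  X <- oracle_embed(x, m, tau)
  M <- nrow(X)
  R <- matrix(FALSE, M, M)
  for (i in seq_len(M))
    for (j in seq_len(M))
      if (i != j) R[i, j] <- oracle_dist(X[i, ], X[j, ], "euclidean") <= r
  nrec <- 0
  for (i in seq_len(M)) for (j in seq_len(M)) if (j > i && R[i, j]) nrec <- nrec + 1
  lens <- integer(0)
  for (k in seq_len(M - 1)) {
    run <- 0
    for (i in seq_len(M - k)) {
      if (R[i, i + k]) run <- run + 1
      else { if (run >= lmin) lens <- c(lens, run); run <- 0 }
    }
    if (run >= lmin) lens <- c(lens, run)
  }
  REC <- 100 * 2 * nrec / (M * (M - 1))
  if (nrec == 0)
    return(list(Lmin = NaN, Lmean = NaN, Lmax = NaN, DIV = NaN,
                REC = 0, DET = NaN, ShanEn = NaN))
  if (length(lens) == 0)
    return(list(Lmin = NaN, Lmean = NaN, Lmax = NaN, DIV = NaN,
                REC = REC, DET = 0, ShanEn = NaN))
  h <- table(lens)
  p <- as.numeric(h) / length(lens)
  list(Lmin = min(lens), Lmean = mean(lens), Lmax = max(lens),
       DIV = 1 / max(lens), REC = REC,
       DET = 100 * sum(lens) / nrec,
       ShanEn = -sum(p * log(p)))
}

# ApEn by direct double-loop template counting (self-matches included).
oracle_apen <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    M <- N - mm + 1
    X <- oracle_embed(x, mm, 1)
    cnt <- numeric(M)
    for (i in seq_len(M))
      for (j in seq_len(M))
        if (oracle_dist(X[i, ], X[j, ], "chebyshev") <= r)
          cnt[i] <- cnt[i] + 1
    mean(log(cnt / M))
  }
  phi(m) - phi(m + 1)
}

# SampEn by direct pair counting over the first N - m templates,
# self-matches excluded.
oracle_sampen <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  count_pairs <- function(mm) {
    X <- oracle_embed(x, mm, 1)[seq_len(nt), , drop = FALSE]
    cnt <- 0
    for (i in seq_len(nt - 1))
      for (j in seq.int(i + 1, nt))
        if (oracle_dist(X[i, ], X[j, ], "chebyshev") <= r) cnt <- cnt + 1
    cnt
  }
  B <- count_pairs(m); A <- count_pairs(m + 1)
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

# Correlation sum by explicit pair enumeration.
oracle_corr_sum <- function(x, m, tau, r) {
  X <- oracle_embed(x, m, tau)
  M <- nrow(X)
  cnt <- 0
  for (i in seq_len(M - 1))
    for (j in seq.int(i + 1, M))
      if (oracle_dist(X[i, ], X[j, ], "euclidean") <= r) cnt <- cnt + 1
  2 * cnt / (M * (M - 1))
}

# A short physiologic-looking RR series for quick tests.
make_rri <- function(n = 300, seed = 1, mean_ms = 857, sd_ms = 25) {
  set.seed(seed)
  x <- mean_ms + sd_ms * sin(2 * pi * 0.1 * seq_len(n) * mean_ms / 1000) +
       stats::rnorm(n, 0, sd_ms / 3)
  rri_series(x)
}
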