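test_that("Poincare geometry matches its closed forms", {
  const <- rri_series(rep(1000, 50))
  p <- poincare(const)
  expect_equal(p$SD1, 0)
  expect_equal(p$SD2, 0)
  expect_true(is.nan(p$SD1_SD2))

  # strict alternation: all short-term, no long-term variability
  alt <- rri_series(rep(c(800, 850), 100))
  pa <- poincare(alt)
  expect_equal(pa$SD1, sqrt(2500 / 2), tolerance = 1e-9)
  expect_equal(pa$SD2, 0, tolerance = 1e-6)
})

test_that("SD1 equals RMSSD/sqrt(2) on every series", {
  for (seed in 1:5) {
    r <- make_rri(200, seed = seed)
    expect_equal(poincare(r)$SD1,
                 time_domain_metrics(r)$RMSSD / sqrt(2),
                 tolerance = 1e-9)
  }
})

test_that("RQA equals the brute-force reference on short seeded series", {
  for (seed in 1:6) {
    set.seed(seed)
    x <- stats::rnorm(30, 1000, 30)
    s <- stats::sd(x)
    got <- rqa(rri_series(x), m = 3, tau = 1, r = sqrt(3) * s)
    want <- oracle_rqa(x, m = 3, tau = 1, r = sqrt(3) * s)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
  }
})

test_that("RQA of a periodic orbit is fully deterministic", {
  x <- rep(c(900, 950, 1000, 1050, 980), 40)  # period 5, 200 beats
  res <- rqa(rri_series(x), m = 3, tau = 1, r = 1)
  M <- 200 - 2
  expect_equal(res$DET, 100)
  expect_equal(res$Lmax, M - 5)  # longest off-diagonal line of a periodic orbit
  expect_equal(res$DIV * res$Lmax, 1)
})

test_that("RQA handles the no-recurrence path", {
  x <- seq(100, 4000, length.out = 40)  # far-apart points, tiny r
  expect_warning(res <- rqa(rri_series(x), m = 2, tau = 1, r = 1e-6),
                 "no recurrent")
  expect_equal(res$REC, 0)
  expect_true(is.nan(res$DET))
})

test_that("entropies equal brute-force template counting", {
  for (seed in 1:6) {
    set.seed(seed)
    x <- stats::rnorm(20, 1000, 25)
    r <- 0.2 * stats::sd(x)
    expect_equal(apen(rri_series(x), 2, r), oracle_apen(x, 2, r),
                 tolerance = 1e-12)
    got_se <- suppressWarnings(sampen(rri_series(x), 2, r))
    want_se <- oracle_sampen(x, 2, r)
    if (is.nan(want_se)) expect_true(is.nan(got_se))
    else expect_equal(got_se, want_se, tolerance = 1e-12)
  }
})

test_that("SampEn of an exactly periodic series is zero", {
  x <- rep(c(900, 1000, 1100), 20)
  expect_equal(sampen(rri_series(x)), 0, tolerance = 1e-12)
})

test_that("entropies are invariant to adding a constant", {
  set.seed(7)
  x <- stats::rnorm(60, 1000, 30)
  expect_equal(apen(rri_series(x)), apen(rri_series(x + 500)),
               tolerance = 1e-12)
  expect_equal(sampen(rri_series(x)), sampen(rri_series(x + 500)),
               tolerance = 1e-12)
})

test_that("correlation sum matches pair enumeration and edge cases", {
  # 4 identical embedded points: fraction convention gives 1; the printed
  # 1/(N(N-1)) prefactor with an i<j sum would give 0.5
  x <- rep(1000, 5)
  expect_equal(correlation_sum(x, m = 2, r = 1), 1)
  M <- 4; cnt <- M * (M - 1) / 2
  expect_equal((1 / (M * (M - 1))) * cnt, 0.5)

  set.seed(8)
  y <- stats::rnorm(12, 1000, 50)
  expect_equal(correlation_sum(y, m = 2, r = 1e-9), 0)
  rs <- exp(seq(log(1), log(200), length.out = 20))
  got <- correlation_sum(y, m = 3, tau = 1, r = rs)
  want <- vapply(rs, function(rr) oracle_corr_sum(y, 3, 1, rr), numeric(1))
  expect_equal(got, want, tolerance = 1e-15)

  expect_error(correlation_sum(y, m = 2, r = -1), "positive")
})

test_that("DFA matches its exact finite-sample expectation on white noise", {
  # For uncorrelated noise the expected squared fluctuation in a box of
  # size n has the closed form tr((I-H) S (I-H)) / n, with S the Brownian
  # covariance min(i,j) and H the linear-fit hat matrix. The log-log slope
  # of that expectation over boxes 4..16 is ~0.583, not the asymptotic 0.5:
  # the well-known small-scale bias of DFA-1. The estimator must reproduce
  # its own expectation, and the asymptotic 0.5 at the long-range scales.
  exact_F <- function(n) {
    t <- seq_len(n)
    A <- cbind(1, t)
    H <- A %*% solve(crossprod(A), t(A))
    S <- outer(t, t, pmin)
    R <- diag(n) - H
    sqrt(sum(diag(R %*% S %*% t(R))) / n)
  }
  sizes <- 4:16
  fw <- vapply(sizes, exact_F, numeric(1))
  expected_slope <- stats::coef(stats::lm(log(fw) ~ log(sizes)))[[2]]
  expect_equal(expected_slope, 0.583, tolerance = 0.01)

  set.seed(9)
  w <- stats::rnorm(10000)
  a_white <- dfa(w + 1000)
  expect_equal(a_white$alpha1, expected_slope, tolerance = 0.05)
  expect_equal(a_white$alpha2, 0.5, tolerance = 0.05)

  b <- cumsum(stats::rnorm(10000))
  a_brown <- dfa(b - min(b) + 1)
  expect_equal(a_brown$alpha1, 1.5, tolerance = 0.08)
})

test_that("DFA is scale invariant and rejects degenerate input", {
  r <- make_rri(400, seed = 10)
  a1 <- dfa(r)
  a2 <- dfa(rri_series(r$intervals * 3.7))
  expect_equal(a1$alpha1, a2$alpha1, tolerance = 1e-9)
  expect_equal(a1$alpha2, a2$alpha2, tolerance = 1e-9)
  expect_error(dfa(rep(1000, 200)), "constant")
  expect_error(dfa(rep(1000, 50)), "at least")
})

test_that("correlation dimension separates limit cycle from noise", {
  set.seed(15)
  cyc <- ipfm_generate(generator_params(target_HR = 70, a_LF = 0.05,
                                        a_HF = 0, noise_sd = 0,
                                        duration = 1100))
  d_cycle <- cordim(cyc)
  expect_equal(d_cycle, 1.0, tolerance = 0.15)

  set.seed(16)
  d_noise <- cordim(stats::rnorm(400, 1000, 30))
  expect_gt(d_noise, d_cycle)

  expect_equal(cordim(rep(1000, 200)), 0)
})

test_that("RQA and entropies are invariant to constant shifts (r tied to SD)", {
  set.seed(17)
  x <- stats::rnorm(80, 900, 40)
  a <- rqa(rri_series(x), m = 3)
  b <- rqa(rri_series(x + 300), m = 3)
  for (nm in names(a)) expect_equal(a[[nm]], b[[nm]], tolerance = 1e-12)
})
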