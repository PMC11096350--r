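make_stats_cohort <- function(n = 30, delta = 0, seed = 1) {
  set.seed(seed)
  data.frame(group = rep(c("dcSSc", "lcSSc"), each = n),
             v = c(stats::rnorm(n, delta), stats::rnorm(n)))
}

test_that("univariate comparison picks the right test and finds the effect", {
  coh <- make_stats_cohort(30, delta = 5, seed = 51)
  res <- univariate_compare(coh, "v")
  expect_equal(res$test_name, "welch_t")
  expect_lt(res$p_unadjusted, 1e-6)
  # cross-check against the reference implementation
  ref <- stats::t.test(v ~ group, data = coh)
  expect_equal(res$p_unadjusted, ref$p.value, tolerance = 1e-12)

  null <- make_stats_cohort(30, delta = 0, seed = 52)
  expect_gt(univariate_compare(null, "v")$p_unadjusted, 0.05)

  skewed <- make_stats_cohort(40, seed = 53)
  skewed$v <- exp(skewed$v * 2)
  res_sk <- univariate_compare(skewed, "v")
  expect_equal(res_sk$test_name, "mann_whitney")
  ref_w <- stats::wilcox.test(v ~ group, data = skewed, exact = FALSE)
  expect_equal(res_sk$p_unadjusted, ref_w$p.value, tolerance = 1e-12)
})

test_that("categorical comparison switches between Fisher and chi-square", {
  res <- categorical_compare(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$test_name, "fisher_exact")
  expect_lt(res$p_unadjusted, 0.001)
  expect_equal(res$p_unadjusted,
               stats::fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value,
               tolerance = 1e-12)

  even <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(categorical_compare(even)$p_unadjusted, 1)

  big <- matrix(c(30, 25, 28, 33), 2)
  res_b <- categorical_compare(big)
  expect_equal(res_b$test_name, "chi_square")
  expect_gt(res_b$p_unadjusted, 0.05)
  expect_error(categorical_compare(matrix(0, 2, 2)), "all-zero")
})

test_that("mixed ANOVA isolates position, group and interaction effects", {
  set.seed(54)
  n <- 40
  base <- stats::rnorm(n, 900, 30)
  # pure position effect: everyone shifts +100 on stand-up
  coh <- data.frame(group = rep(c("dcSSc", "lcSSc"), each = n / 2),
                    x_S1 = base, x_S2 = base + 100 + stats::rnorm(n, 0, 5))
  res <- mixed_anova(coh, "x")
  expect_equal(res$effect, c("clinical_form", "position", "interaction"))
  expect_lt(res$p_adjusted[res$effect == "position"], 0.01)
  expect_gt(res$p_adjusted[res$effect == "clinical_form"], 0.5)
  expect_gt(res$p_adjusted[res$effect == "interaction"], 0.5)
  expect_true(all(res$p_adjusted >= res$p_unadjusted))

  # crossover: deltas of opposite sign by group -> interaction
  coh2 <- coh
  coh2$x_S2 <- base + ifelse(coh2$group == "dcSSc", -60, 60) +
               stats::rnorm(n, 0, 5)
  res2 <- mixed_anova(coh2, "x")
  expect_lt(res2$p_adjusted[res2$effect == "interaction"], 0.05)
})

test_that("rank-based factorial fallback engages on non-normal residuals", {
  set.seed(55)
  n <- 40
  coh <- data.frame(group = rep(c("dcSSc", "lcSSc"), each = n / 2),
                    x_S1 = exp(stats::rnorm(n, 0, 1.5)),
                    x_S2 = exp(stats::rnorm(n, 2, 1.5)))
  res <- mixed_anova(coh, "x")
  expect_equal(unique(res$statistic_type), "H")
  expect_lt(res$p_adjusted[res$effect == "position"], 0.05)
})

test_that("label permutation of null data keeps adjusted p mostly > 0.05", {
  set.seed(56)
  n <- 40
  base <- stats::rnorm(n, 900, 30)
  coh <- data.frame(group = rep(c("dcSSc", "lcSSc"), each = n / 2),
                    x_S1 = base, x_S2 = base + stats::rnorm(n, 0, 20))
  hits <- vapply(1:40, function(i) {
    set.seed(56 + i)
    perm <- coh
    perm$group <- sample(perm$group)
    any(mixed_anova(perm, "x")$p_adjusted < 0.05)
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("correlation matrix applies the normality gate and masks p >= .05", {
  set.seed(57)
  n <- 50
  x <- stats::rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.64) * stats::rnorm(n)
  coh <- data.frame(a = x, b = y, c = -x, noise = stats::rnorm(n))
  cm <- correlation_matrix(coh, c("a", "b", "c", "noise"))
  expect_equal(diag(cm$R), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm$R["a", "c"], -1, tolerance = 1e-12)
  expect_equal(cm$R["a", "b"],
               unname(stats::cor.test(x, y)$estimate), tolerance = 1e-12)
  expect_true(cm$R["a", "b"] > 0.6 && cm$R["a", "b"] < 0.95)
  expect_true(is.na(cm$R_masked["a", "noise"]))
  expect_equal(cm$method["a", "b"], "pearson")
})
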