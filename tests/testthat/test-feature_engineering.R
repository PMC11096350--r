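# A small planted-signal cohort: `n_info` informative features with group
# separation `effect` (in SD units), the rest pure noise.
planted_cohort <- function(n = 60, n_info = 10, n_noise = 20, effect = 2,
                           seed = 1) {
  set.seed(seed)
  g <- rep(c("dcSSc", "lcSSc"), each = n / 2)
  X <- matrix(stats::rnorm(n * (n_info + n_noise)), n)
  X[g == "dcSSc", seq_len(n_info)] <- X[g == "dcSSc", seq_len(n_info)] + effect
  colnames(X) <- c(sprintf("info%02d", seq_len(n_info)),
                   sprintf("noise%02d", seq_len(n_noise)))
  cbind(data.frame(group = g), as.data.frame(X))
}

test_that("univariate screening keeps signal and drops flat features", {
  coh <- planted_cohort(seed = 61)
  coh$flat <- 1:nrow(coh) * 0 + 5
  feats <- c(colnames(coh)[-1])
  kept <- screen_univariate(coh, feats)
  expect_false("flat" %in% kept)
  expect_gte(sum(grepl("^info", kept)), 8)
  expect_lte(sum(grepl("^noise", kept)), 4)
})

test_that("collinearity pruning removes exactly one member per pair", {
  coh <- planted_cohort(seed = 62)
  coh$dup_delta <- coh$info01  # duplicated column
  res <- prune_collinear(coh, c("info01", "dup_delta", "noise01"))
  expect_length(res$keep, 2)
  expect_equal(nrow(res$removed), 1)
  expect_true(xor("info01" %in% res$keep, "dup_delta" %in% res$keep))
  # delta-suffixed features are preferred over plain ones
  expect_true("dup_delta" %in% res$keep)

  ortho <- prune_collinear(coh, c("noise01", "noise02", "noise03"))
  expect_length(ortho$keep, 3)
})

test_that("SD1 and RMSSD are pruned as perfectly collinear on any cohort", {
  dir <- withr::local_tempdir()
  cc <- make_cohort(cohort_preset(n_dc = 3, n_lc = 3), seed = 6, dir = dir)
  tab <- build_cohort(cc$manifest)$table
  res <- prune_collinear(tab, c("SD1_S1", "RMSSD_S1"))
  expect_length(res$keep, 1)
  expect_equal(res$removed$r2, 1, tolerance = 1e-9)
})

test_that("pruning survivors are invariant to row shuffling", {
  coh <- planted_cohort(seed = 63)
  feats <- colnames(coh)[-1]
  a <- prune_collinear(coh, feats)
  set.seed(1); coh2 <- coh[sample(nrow(coh)), ]
  b <- prune_collinear(coh2, feats)
  expect_equal(sort(a$keep), sort(b$keep))
})

test_that("min-max scaling maps to [0,1] and drops constants", {
  coh <- planted_cohort(seed = 64)
  coh$const <- 7
  expect_warning(sc <- minmax_scale(coh, c("info01", "noise01", "const")),
                 "constant")
  expect_equal(names(sc), c("info01", "noise01"))
  expect_equal(range(sc$info01), c(0, 1))
})

test_that("a single dominant feature wins the aggregated ranking", {
  coh <- planted_cohort(n_info = 1, n_noise = 10, effect = 4, seed = 65)
  rt <- rank_features(coh, colnames(coh)[-1], seed = 5)
  expect_equal(rt$feature[1], "info01")
  expect_equal(rt$final_rank, seq_len(nrow(rt)))
  expect_equal(rt$redundancy_score, rt$mean_rank + rt$rank_sd,
               tolerance = 1e-12)
  # per-selector ranks are permutations
  for (col in c("bagged_trees", "extra_trees", "f_score", "mutual_info",
                "rfe_linear"))
    expect_setequal(rt[[col]], seq_len(nrow(rt)))
  # deterministic rerun
  rt2 <- rank_features(coh, colnames(coh)[-1], seed = 5)
  expect_identical(rt$feature, rt2$feature)
})

test_that("gamma separability matches its formula and invariances", {
  coh <- planted_cohort(n_info = 1, n_noise = 2, effect = 0, seed = 66)
  g0 <- gamma_rank(coh, c("info01", "noise01"))
  expect_true(all(g0$gamma < 0.5))

  set.seed(67)
  n <- 200
  coh2 <- data.frame(group = rep(c("dcSSc", "lcSSc"), each = n),
                     v = c(stats::rnorm(n, 3, 1), stats::rnorm(n, 0, 1)))
  gv <- gamma_rank(coh2, "v")$gamma
  expect_equal(gv, 3 / sqrt(2), tolerance = 0.15)
  coh2$v <- coh2$v + 100
  expect_equal(gamma_rank(coh2, "v")$gamma, gv, tolerance = 1e-12)
})

test_that("top-k selection blends consensus and arbiter slots", {
  rt <- data.frame(feature = c("a", "b", "c", "d", "e", "f"),
                   redundancy_score = 1:6)
  gt <- data.frame(feature = c("a", "b", "c", "d", "x", "f"),
                   gamma = 6:1)
  sel <- select_top(rt, gt, n_top = 5)
  expect_equal(sel$automatic, c("a", "b", "c", "d"))
  expect_length(sel$selected, 5)
  expect_equal(sel$arbitrated, "e")  # redundancy order fills the free slot

  manual <- select_top(rt, gt, n_top = 5, arbiter = "x")
  expect_equal(manual$selected, c("a", "b", "c", "d", "x"))

  same <- select_top(rt, gt[match(rt$feature, gt$feature) |> na.omit(), ],
                     n_top = 3)
  expect_error(select_top(rt, gt, n_top = 10), "exceeds")
})

test_that("planted discriminative features dominate the final top-5", {
  wins <- vapply(1:10, function(i) {
    coh <- planted_cohort(n = 400, n_info = 5, n_noise = 15, effect = 1.5,
                          seed = 600 + i)
    rt <- rank_features(coh, colnames(coh)[-1], seed = i)
    gt <- gamma_rank(coh, colnames(coh)[-1])
    sel <- select_top(rt, gt, n_top = 5)
    sum(grepl("^info", sel$selected))
  }, numeric(1))
  expect_gte(mean(wins >= 4), 0.9)
})
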