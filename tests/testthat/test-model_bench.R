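two_class_data <- function(n_pos = 20, n_neg = 40, sep = 3, seed = 1,
                           p = 3) {
  set.seed(seed)
  X <- matrix(stats::rnorm((n_pos + n_neg) * p), ncol = p)
  X[seq_len(n_pos), 1] <- X[seq_len(n_pos), 1] + sep
  y <- factor(c(rep("dcSSc", n_pos), rep("lcSSc", n_neg)))
  list(X = X, y = y)
}

test_that("SMOTE reaches parity with convex synthetic points", {
  d <- two_class_data(n_pos = 4, n_neg = 10, seed = 71)
  out <- smote(d$X, d$y, k = 3, seed = 2)
  expect_equal(unname(table(out$y)), c(10L, 10L), ignore_attr = TRUE)
  expect_equal(sum(out$synthetic), 6)
  # every synthetic point lies on a segment between two minority points
  Xm <- d$X[d$y == "dcSSc", ]
  syn <- out$X[out$synthetic, , drop = FALSE]
  for (i in seq_len(nrow(syn))) {
    colinear <- FALSE
    for (a in seq_len(nrow(Xm) - 1)) for (b in seq.int(a + 1, nrow(Xm))) {
      v1 <- Xm[b, ] - Xm[a, ]; v2 <- syn[i, ] - Xm[a, ]
      lam <- sum(v1 * v2) / sum(v1 * v1)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((v2 - lam * v1)^2)) < 1e-9) colinear <- TRUE
    }
    expect_true(colinear)
  }
})

test_that("SMOTE passes balanced input through and bounds 1-D output", {
  d <- two_class_data(n_pos = 10, n_neg = 10, seed = 72)
  out <- smote(d$X, d$y)
  expect_identical(out$X, as.matrix(d$X))

  X1 <- matrix(c(0, 1, rep(5, 8)), ncol = 1)
  y1 <- factor(c("a", "a", rep("b", 8)))
  expect_warning(o1 <- smote(X1, y1, k = 5, seed = 3), "k reduced")
  expect_true(all(o1$X[o1$synthetic, 1] >= 0 & o1$X[o1$synthetic, 1] <= 1))
  expect_error(smote(X1, factor(rep("a", 10))), "two classes")
})

test_that("combination enumeration matches the closed-form counts", {
  expect_length(generate_combinations(letters[1:5]), 31)
  expect_length(generate_combinations("a"), 1)
  expect_length(generate_combinations(letters[1:3]), 7)
  expect_equal(count_possible_combinations(24, 5), 55454)
  expect_equal(count_possible_combinations(5, 5), 31)
  expect_equal(count_possible_combinations(3, 5 - 2), 7)
  expect_error(generate_combinations(character(0)), "empty")
})

test_that("stratified split partitions and preserves class balance", {
  coh <- data.frame(group = c(rep("dcSSc", 16), rep("lcSSc", 42)))
  sp <- split_cohort(coh, seed = 4)
  expect_setequal(c(sp$train, sp$validation), 1:58)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_true(length(sp$train) %in% 46:47)
  tr_g <- coh$group[sp$train]
  expect_true(all(table(coh$group[sp$validation]) >= 1))
  expect_equal(sum(tr_g == "dcSSc"), 13)  # round(0.8 * 16)
  sp2 <- split_cohort(coh, seed = 4)
  expect_identical(sp, sp2)
})

test_that("the 8 scores equal hand-computed confusion-matrix values", {
  # TP=9 FN=1 TN=7 FP=3
  truth <- factor(c(rep("pos", 10), rep("neg", 10)),
                  levels = c("neg", "pos"))
  prob <- c(rep(0.9, 9), 0.1, rep(0.2, 7), rep(0.8, 3))
  s <- score_predictions(prob, truth)
  expect_equal(unname(s["Sensitivity"]), 0.9)
  expect_equal(unname(s["Specificity"]), 0.7)
  expect_equal(unname(s["Precision"]), 0.75)
  expect_equal(unname(s["Accuracy"]), 0.8)
  expect_equal(unname(s["F1"]), 2 * 0.75 * 0.9 / (0.75 + 0.9),
               tolerance = 1e-12)
  expect_equal(unname(s["MSE"]),
               mean((prob - rep(c(1, 0), c(10, 10)))^2), tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref_auc <- suppressMessages(
    as.numeric(pROC::auc(as.numeric(truth == "pos"), prob)))
  expect_equal(unname(s["AUC"]), ref_auc, tolerance = 1e-12)
})

test_that("every registered algorithm fits and scores separable data", {
  d <- two_class_data(n_pos = 15, n_neg = 30, sep = 6, seed = 73)
  coh <- cbind(data.frame(group = as.character(d$y)), as.data.frame(d$X))
  sp <- split_cohort(coh, seed = 7)
  aucs <- vapply(algorithm_registry(), function(alg) {
    res <- suppressWarnings(
      evaluate_model(c("V1", "V2"), alg, coh, sp$train, sp$validation,
                     cv_repeats = 0, seed = 11))
    expect_true(all(res$validation[c("MSE", "LogLoss")] >= 0))
    unname(res$validation["AUC"])
  }, numeric(1))
  expect_true(all(aucs >= 0.8))       # every family learns the separation
  expect_gte(sum(aucs == 1), 9)       # most rank the validation perfectly
})

test_that("label-permuted data yields chance-level AUC", {
  aucs <- vapply(1:12, function(i) {
    d <- two_class_data(n_pos = 20, n_neg = 20, sep = 0, seed = 700 + i)
    coh <- cbind(data.frame(group = as.character(d$y)), as.data.frame(d$X))
    sp <- split_cohort(coh, train_frac = 0.7, seed = i)
    res <- suppressWarnings(
      evaluate_model("V1", "logistic_regression", coh, sp$train,
                     sp$validation, cv_repeats = 0, seed = i))
    unname(res$validation["AUC"])
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.12)
})

test_that("CV reporting and the within-fold SMOTE leakage guard work", {
  d <- two_class_data(n_pos = 12, n_neg = 24, sep = 2, seed = 74)
  coh <- cbind(data.frame(group = as.character(d$y)), as.data.frame(d$X))
  sp <- split_cohort(coh, seed = 8)
  res <- suppressWarnings(
    evaluate_model(c("V1", "V2"), "logistic_regression", coh, sp$train,
                   sp$validation, cv_k = 3, cv_repeats = 2, seed = 9))
  expect_length(res$cv_mean, 8)
  expect_length(res$cv_sd, 8)
  expect_true(all(res$cv_sd >= 0))

  # leakage guard: held-out fold indices never include synthetic rows,
  # because balancing happens strictly inside the training folds
  y <- factor(coh$group[sp$train])
  folds <- hrvpc:::stratified_folds(y, k = 3, seed = 1)
  expect_setequal(unlist(folds), seq_along(y))
  bal <- smote(d$X[sp$train, ], y, seed = 1)
  expect_true(all(!bal$synthetic[unlist(folds)]))
})

test_that("run_benchmark covers the grid and reports the best per combination", {
  d <- two_class_data(n_pos = 12, n_neg = 24, sep = 3, seed = 75)
  coh <- cbind(data.frame(group = as.character(d$y)), as.data.frame(d$X))
  bm <- suppressWarnings(
    run_benchmark(coh, c("V1", "V2"),
                  algorithms = c("logistic_regression", "decision_tree"),
                  seed = 10))
  expect_equal(nrow(bm$grid), 6)  # 3 combos x 2 algorithms
  expect_equal(nrow(bm$best_per_combination), 3)
  expect_null(bm$failed)
})
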