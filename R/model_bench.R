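# Combinatorial classifier benchmark: SMOTE balancing, all 1..5-variable
# feature combinations, 11 classifier families, repeated stratified CV,
# 8 performance metrics. Positive class = dcSSc (the clinical target).

#' The fixed classifier registry
#'
#' @return Character vector of the 11 algorithm names.
#' @export
algorithm_registry <- function() {
  c("logistic_regression", "decision_tree", "random_forest", "linear_svm",
    "rbf_svm", "neural_network", "gbm", "stacked_ensemble", "extra_trees",
    "knn", "xgboost")
}

# Class labels as a factor whose SECOND level is the positive class.
# For the dcSSc/lcSSc pair the diffuse form (the clinical target and
# minority class) is positive; any other labelling keeps factor order.
group_factor <- function(g) {
  g <- as.character(g)
  if (setequal(unique(g), c("dcSSc", "lcSSc")))
    factor(g, levels = c("lcSSc", "dcSSc"))
  else factor(g)
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Oversamples the minority class to parity with the majority: each
#' synthetic row is `x + u * (x_nn - x)` with `u ~ U(0, 1)` and `x_nn` one
#' of the `k` nearest minority neighbours of `x` (Euclidean distance).
#' Original rows are passed through unchanged. Already balanced input is
#' returned as-is.
#'
#' @param X Numeric matrix or data.frame of (scaled) features.
#' @param y Factor of class labels (2 levels).
#' @param k Number of minority neighbours (default 5; auto-reduced with a
#'   warning when the minority class is too small).
#' @param seed Integer seed.
#' @return List `X` (matrix), `y` (factor), `synthetic` (logical marker per
#'   row).
#' @export
smote <- function(X, y, k = 5, seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2) stop("smote: need exactly two classes")
  tab <- table(y)
  if (min(tab) == 0) stop("smote: single-class input")
  if (tab[1] == tab[2])
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  minority <- names(tab)[which.min(tab)]
  Xm <- X[y == minority, , drop = FALSE]
  n_min <- nrow(Xm)
  n_new <- max(tab) - n_min
  if (n_min < 2) stop("smote: minority class must have >= 2 members")
  if (n_min < k + 1) {
    k <- n_min - 1
    warning("smote: minority too small; k reduced to ", k)
  }
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn_raw <- apply(D, 1, function(d) order(d)[seq_len(k)])
  nn_idx <- if (k == 1) matrix(nn_raw, ncol = 1) else t(nn_raw)
  set.seed(seed)
  base_idx <- rep_len(seq_len(n_min), n_new)
  syn <- t(vapply(base_idx, function(i) {
    j <- nn_idx[i, sample.int(k, 1)]
    u <- stats::runif(1)
    Xm[i, ] + u * (Xm[j, ] - Xm[i, ])
  }, numeric(ncol(X))))
  if (ncol(X) == 1L) syn <- matrix(as.numeric(syn), ncol = 1L)
  colnames(syn) <- colnames(X)
  list(X = rbind(X, syn),
       y = factor(c(as.character(y), rep(minority, n_new)),
                  levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)))
}

#' Enumerate feature combinations
#'
#' All subsets of sizes 1..`max_size`, in deterministic lexicographic order
#' (size-major).
#'
#' @param features Character vector of feature names.
#' @param max_size Largest subset size (default 5).
#' @return List of character vectors.
#' @export
generate_combinations <- function(features, max_size = 5) {
  if (length(features) == 0) stop("generate_combinations: empty feature set")
  features <- sort(features)
  out <- list()
  for (s in seq_len(min(max_size, length(features)))) {
    cmb <- utils::combn(features, s, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Count feature combinations of size 1..max_size
#'
#' `sum_{i=1..max_size} C(n, i)`; 24 candidates give 55454, 5 give 31.
#'
#' @param n Number of candidate features.
#' @param max_size Largest subset size (default 5).
#' @return Integer count.
#' @export
count_possible_combinations <- function(n, max_size = 5) {
  stopifnot(n >= max_size)
  sum(choose(n, seq_len(max_size)))
}

#' Stratified train/validation split
#'
#' @param cohort Data frame with a `group` column.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List `train`, `validation` (row indices).
#' @export
split_cohort <- function(cohort, train_frac = 0.8, seed = 1) {
  g <- factor(cohort$group)
  if (min(table(g)) < 2)
    stop("split_cohort: each class needs >= 2 members")
  set.seed(seed)
  tr <- integer(0)
  for (lv in levels(g)) {
    idx <- which(g == lv)
    n_tr <- round(train_frac * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    tr <- c(tr, sample(idx, n_tr))
  }
  tr <- sort(tr)
  list(train = tr, validation = setdiff(seq_len(nrow(cohort)), tr))
}

# ---- classifier fitting: each returns function(newX) -> P(positive) ----

fit_classifier <- function(algorithm, X, y, seed) {
  X <- as.matrix(X)
  pos <- levels(y)[2]  # positive class is the second level
  yy <- as.numeric(y == pos)
  set.seed(seed)
  switch(algorithm,
    logistic_regression = {
      df <- data.frame(X); df$.y <- yy
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                         family = stats::binomial()))
      function(newX) {
        suppressWarnings(as.numeric(stats::predict(
          fit, newdata = data.frame(as.matrix(newX)), type = "response")))
      }
    },
    decision_tree = {
      df <- data.frame(X); df$.y <- y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 5,
                                                         cp = 0.01))
      function(newX)
        as.numeric(stats::predict(fit,
          newdata = data.frame(as.matrix(newX)), type = "prob")[, pos])
    },
    random_forest = {
      fit <- ranger::ranger(x = X, y = y, num.trees = 300,
                            probability = TRUE, seed = seed)
      function(newX)
        as.numeric(stats::predict(fit,
          data = as.matrix(newX))$predictions[, pos])
    },
    extra_trees = {
      fit <- ranger::ranger(x = X, y = y, num.trees = 300,
                            splitrule = "extratrees", num.random.splits = 1,
                            probability = TRUE, seed = seed)
      function(newX)
        as.numeric(stats::predict(fit,
          data = as.matrix(newX))$predictions[, pos])
    },
    linear_svm = ,
    rbf_svm = {
      kern <- if (algorithm == "linear_svm") "linear" else "radial"
      fit <- e1071::svm(x = X, y = y, kernel = kern, probability = TRUE)
      function(newX) {
        pr <- stats::predict(fit, newdata = as.matrix(newX),
                             probability = TRUE)
        as.numeric(attr(pr, "probabilities")[, pos])
      }
    },
    neural_network = {
      fit <- nnet::nnet(x = X, y = yy, size = 4, decay = 0.1, maxit = 300,
                        trace = FALSE)
      function(newX) as.numeric(stats::predict(fit, as.matrix(newX)))
    },
    gbm = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.1, subsample = 0.8, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = yy), nrounds = 150)
      function(newX) as.numeric(stats::predict(
        fit, xgboost::xgb.DMatrix(as.matrix(newX))))
    },
    xgboost = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 6,
                      eta = 0.3, nthread = 1),
        data = xgboost::xgb.DMatrix(X, label = yy), nrounds = 60)
      function(newX) as.numeric(stats::predict(
        fit, xgboost::xgb.DMatrix(as.matrix(newX))))
    },
    knn = {
      k_use <- min(5L, nrow(X) - 1L)
      function(newX) {
        pr <- class::knn(train = X, test = as.matrix(newX), cl = y,
                         k = k_use, prob = TRUE)
        p_win <- attr(pr, "prob")
        ifelse(pr == pos, p_win, 1 - p_win)
      }
    },
    stacked_ensemble = {
      # base learners: logistic + random forest + gbm; logistic meta-model
      # trained on out-of-fold base predictions
      base_algos <- c("logistic_regression", "random_forest", "gbm")
      folds <- stratified_folds(y, k = min(5L, min(table(y))), seed = seed)
      oof <- matrix(NA_real_, nrow(X), length(base_algos))
      for (f in seq_along(folds)) {
        hold <- folds[[f]]
        for (b in seq_along(base_algos)) {
          pf <- fit_classifier(base_algos[b], X[-hold, , drop = FALSE],
                               droplevels(y[-hold]), seed + f)
          oof[hold, b] <- pf(X[hold, , drop = FALSE])
        }
      }
      meta <- suppressWarnings(stats::glm(yy ~ .,
        data = data.frame(oof), family = stats::binomial()))
      base_fits <- lapply(base_algos, function(a)
        fit_classifier(a, X, y, seed))
      function(newX) {
        bp <- vapply(base_fits, function(f) f(newX),
                     numeric(nrow(as.matrix(newX))))
        bp <- matrix(bp, ncol = length(base_fits))
        colnames(bp) <- colnames(oof) <- paste0("X", seq_along(base_fits))
        suppressWarnings(as.numeric(stats::predict(
          meta, newdata = data.frame(bp), type = "response")))
      }
    },
    stop("fit_classifier: unknown algorithm ", algorithm)
  )
}

# Stratified k-fold partition of indices; returns list of held-out index
# vectors.
stratified_folds <- function(y, k = 5, seed = 1) {
  set.seed(seed)
  folds <- vector("list", k)
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    assign_f <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assign_f == f])
  }
  lapply(folds, sort)
}

#' Classification performance metrics
#'
#' The 8 benchmark metrics from predicted positive-class probabilities and
#' true labels, thresholding at 0.5: Brier-style MSE, log loss (clipped at
#' 1e-15), sensitivity, specificity, precision, accuracy, trapezoidal ROC
#' AUC, and F1 (harmonic mean of precision and sensitivity).
#'
#' @param prob Predicted probabilities of the positive class.
#' @param truth Factor of true labels; the second level is positive.
#' @return Named numeric vector of the 8 metrics.
#' @export
score_predictions <- function(prob, truth) {
  truth <- factor(truth)
  pos <- levels(truth)[2]
  ybin <- as.numeric(truth == pos)
  prob <- pmin(pmax(prob, 0), 1)
  pred <- as.numeric(prob >= 0.5)
  tp <- sum(pred == 1 & ybin == 1); fn <- sum(pred == 0 & ybin == 1)
  tn <- sum(pred == 0 & ybin == 0); fp <- sum(pred == 1 & ybin == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  acc <- (tp + tn) / length(ybin)
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
          2 * prec * sens / (prec + sens) else NA_real_
  pc <- pmin(pmax(prob, 1e-15), 1 - 1e-15)
  c(MSE = mean((prob - ybin)^2),
    LogLoss = -mean(ybin * log(pc) + (1 - ybin) * log(1 - pc)),
    Sensitivity = sens, Specificity = spec, Precision = prec,
    Accuracy = acc, AUC = auc_trapezoid(prob, ybin), F1 = f1)
}

# Trapezoidal ROC AUC; equals the Mann-Whitney statistic with ties counted
# half.
auc_trapezoid <- function(prob, ybin) {
  n1 <- sum(ybin == 1); n0 <- sum(ybin == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[ybin == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate one (feature combination, algorithm) cell
#'
#' Fits the algorithm on the (optionally SMOTE-balanced) training rows and
#' scores the held-out validation rows; optionally adds repeated stratified
#' k-fold cross-validation on the training set, reporting the CV mean and
#' SD per metric. Under `smote_policy = "within_folds"` (default) SMOTE is
#' applied inside each CV training fold only, so no synthetic sample ever
#' reaches a held-out fold; `"before_split"` balances the training set once
#' before CV (a known leakage risk, provided for comparability).
#'
#' @param combination Character vector of feature names (1..5).
#' @param algorithm One of [algorithm_registry()].
#' @param cohort Data frame with the features and a `group` column whose
#'   second factor level is the positive class.
#' @param train,validation Row-index vectors (see [split_cohort()]).
#' @param cv_k Folds (default 5). @param cv_repeats Repeats (default 10;
#'   0 skips CV).
#' @param smote_policy `"within_folds"`, `"before_split"`, or `"none"`.
#' @param seed Integer seed.
#' @return List: `combination`, `algorithm`, `validation` (8 metrics),
#'   `cv_mean`, `cv_sd` (8 metrics each, or `NULL` when `cv_repeats = 0`).
#' @export
evaluate_model <- function(combination, algorithm, cohort, train, validation,
                           cv_k = 5, cv_repeats = 10,
                           smote_policy = c("within_folds", "before_split",
                                            "none"),
                           seed = 1) {
  smote_policy <- match.arg(smote_policy)
  stopifnot(all(combination %in% names(cohort)))
  y <- group_factor(cohort$group)
  X <- as.matrix(cohort[, combination, drop = FALSE])
  Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
  Xva <- X[validation, , drop = FALSE]; yva <- y[validation]

  balance <- function(Xb, yb, s) {
    if (smote_policy == "none") list(X = Xb, y = yb)
    else smote(Xb, yb, seed = s)
  }

  tr_bal <- balance(Xtr, ytr, seed)
  pred_fun <- fit_classifier(algorithm, tr_bal$X, tr_bal$y, seed)
  val_scores <- score_predictions(pred_fun(Xva), yva)

  cv_mean <- cv_sd <- NULL
  if (cv_repeats > 0) {
    if (smote_policy == "before_split") {
      Xcv <- tr_bal$X; ycv <- tr_bal$y
    } else {
      Xcv <- Xtr; ycv <- ytr
    }
    per_rep <- matrix(NA_real_, cv_repeats, 8)
    for (rep_i in seq_len(cv_repeats)) {
      folds <- stratified_folds(ycv, k = cv_k, seed = seed + 1000 * rep_i)
      prob <- rep(NA_real_, length(ycv))
      for (f in seq_along(folds)) {
        hold <- folds[[f]]
        Xf <- Xcv[-hold, , drop = FALSE]; yf <- droplevels(ycv[-hold])
        if (smote_policy == "within_folds") {
          bal <- smote(Xf, yf, seed = seed + rep_i + f)
          Xf <- bal$X; yf <- bal$y
        }
        pf <- fit_classifier(algorithm, Xf, yf, seed + rep_i + f)
        prob[hold] <- pf(Xcv[hold, , drop = FALSE])
      }
      per_rep[rep_i, ] <- score_predictions(prob, ycv)
    }
    colnames(per_rep) <- names(val_scores)
    cv_mean <- colMeans(per_rep)
    cv_sd <- apply(per_rep, 2, stats::sd)
  }
  list(combination = combination, algorithm = algorithm,
       validation = val_scores, cv_mean = cv_mean, cv_sd = cv_sd)
}

#' Run the full combinatorial benchmark
#'
#' Evaluates every (combination x algorithm) cell over all 1..`max_size`
#' subsets of the selected features, and summarises the best algorithm per
#' combination by validation F1.
#'
#' @param cohort Data frame with features and `group`.
#' @param selected_features Character vector of selected features.
#' @param algorithms Algorithm names (default: all 11).
#' @param max_size Largest combination size (default 5).
#' @param train_frac Training fraction for the stratified split.
#' @param cv_repeats CV repeats per cell (default 0: validation-only
#'   scoring; set 10 for full CV dispersion).
#' @param smote_policy See [evaluate_model()].
#' @param seed Integer seed.
#' @return List: `grid` (data.frame, one row per cell with the 8 validation
#'   metrics), `best_per_combination` (best algorithm per combination by
#'   F1), `failed` (data.frame of failed cells, if any).
#' @export
run_benchmark <- function(cohort, selected_features,
                          algorithms = algorithm_registry(), max_size = 5,
                          train_frac = 0.8, cv_repeats = 0,
                          smote_policy = "within_folds", seed = 1) {
  combos <- generate_combinations(selected_features, max_size)
  sp <- split_cohort(cohort, train_frac = train_frac, seed = seed)
  rows <- list(); failed <- list()
  for (ci in seq_along(combos)) {
    for (alg in algorithms) {
      res <- tryCatch(
        evaluate_model(combos[[ci]], alg, cohort, sp$train, sp$validation,
                       cv_repeats = cv_repeats, smote_policy = smote_policy,
                       seed = seed),
        error = function(e) e)
      cmb_lab <- paste(combos[[ci]], collapse = ", ")
      if (inherits(res, "error")) {
        failed[[length(failed) + 1L]] <-
          data.frame(combination = cmb_lab, algorithm = alg,
                     error = conditionMessage(res))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        combination = cmb_lab, n_variables = length(combos[[ci]]),
        algorithm = alg, t(res$validation))
    }
  }
  grid <- do.call(rbind, rows)
  best <- do.call(rbind, lapply(split(grid, grid$combination), function(d) {
    d[order(-d$F1, -d$AUC, d$algorithm)[1], ]
  }))
  best <- best[order(best$n_variables, -best$F1), ]
  rownames(best) <- NULL
  list(grid = grid, best_per_combination = best,
       failed = if (length(failed)) do.call(rbind, failed) else NULL)
}
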