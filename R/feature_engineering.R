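# Feature engineering: univariate screening, collinearity pruning, min-max
# scaling, multi-selector rank aggregation and the gamma separability index.

#' Univariate screening of cohort features
#'
#' Keeps features whose normality-gated two-group comparison (see
#' [univariate_compare()]) has unadjusted p below `alpha`.
#'
#' @param cohort A `cohort_table`.
#' @param features Candidate feature names (default: all 87 columns).
#' @param alpha Screening level (default 0.1).
#' @return Character vector of surviving features.
#' @export
screen_univariate <- function(cohort, features = NULL, alpha = 0.1) {
  if (is.null(features)) features <- setdiff(names(cohort), "group")
  keep <- vapply(features, function(v) {
    p <- tryCatch(univariate_compare(cohort, v)$p_unadjusted,
                  error = function(e) 1)
    isTRUE(p < alpha)
  }, logical(1))
  out <- features[keep]
  if (length(out) == 0L)
    stop("screen_univariate: no feature passes p < ", alpha,
         "; consider relaxing alpha")
  out
}

# Priority used when one member of a collinear pair must be dropped: keep
# stand-up deltas over standing over supine values, then prefer the
# physiologically primary metrics named first in the registry.
keep_priority <- function(features) {
  suffix <- ifelse(grepl("_delta$", features), 0,
                   ifelse(grepl("_S2$", features), 1, 2))
  base <- sub("_(S1|S2|delta)$", "", features)
  reg <- names(hrv_metric_registry())
  reg_rank <- match(base, reg)
  reg_rank[is.na(reg_rank)] <- length(reg) + 1L
  order(order(suffix, reg_rank, features))  # smaller = keep
}

#' Prune collinear feature pairs
#'
#' Greedy single pass over all pairs with squared Pearson correlation above
#' `r2_threshold`, in decreasing R^2 order, removing the lower-priority
#' member of each pair (priority: deltas first, then standing, then supine;
#' ties by registry order then name). Deterministic and independent of row
#' order.
#'
#' @param cohort Data frame holding the features.
#' @param features Feature names (>= 2).
#' @param r2_threshold Squared-correlation threshold (default 0.9).
#' @return List with `keep` (surviving features) and `removed`
#'   (data.frame: removed feature, the partner that kept it out, R^2).
#' @export
prune_collinear <- function(cohort, features, r2_threshold = 0.9) {
  stopifnot(length(features) >= 2)
  X <- as.matrix(cohort[, features, drop = FALSE])
  cc <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))^2
  cc[is.na(cc)] <- 0
  prio <- keep_priority(features)
  pairs <- which(upper.tri(cc) & cc > r2_threshold, arr.ind = TRUE)
  removed <- data.frame(feature = character(0), kept_partner = character(0),
                        r2 = numeric(0))
  if (nrow(pairs)) {
    ord <- order(-cc[pairs])
    pairs <- pairs[ord, , drop = FALSE]
    dead <- character(0)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      fi <- features[i]; fj <- features[j]
      if (fi %in% dead || fj %in% dead) next
      drop_f <- if (prio[i] <= prio[j]) fj else fi
      keep_f <- if (drop_f == fi) fj else fi
      dead <- c(dead, drop_f)
      removed <- rbind(removed,
                       data.frame(feature = drop_f, kept_partner = keep_f,
                                  r2 = cc[i, j]))
    }
    features <- setdiff(features, dead)
  }
  list(keep = features, removed = removed)
}

#' Min-max scale features to [0, 1]
#'
#' Constant features cannot be scaled; they are dropped with a warning.
#'
#' @param cohort Data frame.
#' @param features Feature names.
#' @return Data frame of scaled features (same rows as `cohort`).
#' @export
minmax_scale <- function(cohort, features) {
  out <- lapply(features, function(v) {
    x <- cohort[[v]]
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) return(NULL)
    (x - rng[1]) / diff(rng)
  })
  drop <- features[vapply(out, is.null, logical(1))]
  if (length(drop))
    warning("minmax_scale: dropping constant feature(s): ",
            paste(drop, collapse = ", "))
  keep <- !vapply(out, is.null, logical(1))
  res <- as.data.frame(out[keep], col.names = features[keep])
  names(res) <- features[keep]
  res
}

# --- the five feature selectors; each returns a full ranking (1 = best) ---

rank_desc <- function(score, features) {
  # higher score = better; deterministic tie-break by name
  ord <- order(-score, features)
  r <- integer(length(score)); r[ord] <- seq_along(score)
  r
}

selector_bagged_trees <- function(X, y, seed) {
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = X, y = y, ntree = 300, mtry = ncol(X),  # mtry = p: bagged trees
    importance = FALSE)
  rank_desc(fit$importance[, "MeanDecreaseGini"], colnames(X))
}

selector_extra_trees <- function(X, y, seed) {
  fit <- ranger::ranger(x = X, y = y, num.trees = 300,
                        splitrule = "extratrees", num.random.splits = 1,
                        importance = "impurity", seed = seed)
  rank_desc(fit$variable.importance, colnames(X))
}

selector_f_score <- function(X, y, seed) {
  f <- vapply(seq_len(ncol(X)), function(j) {
    sm <- stats::anova(stats::lm(X[, j] ~ y))
    sm$`F value`[1]
  }, numeric(1))
  rank_desc(f, colnames(X))
}

# Univariate mutual information between an equal-width discretisation of
# each feature and the class label.
selector_mutual_info <- function(X, y, seed, n_bins = 8) {
  mi <- vapply(seq_len(ncol(X)), function(j) {
    b <- cut(X[, j], breaks = n_bins, include.lowest = TRUE)
    tab <- table(b, y)
    pxy <- tab / sum(tab)
    px <- rowSums(pxy); py <- colSums(pxy)
    nz <- pxy > 0
    sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  }, numeric(1))
  rank_desc(mi, colnames(X))
}

# Recursive feature elimination with an L2-regularised linear classifier:
# repeatedly drop the feature with the smallest absolute standardized
# coefficient; rank = elimination order (last survivor ranks 1).
selector_rfe_linear <- function(X, y, seed) {
  feats <- colnames(X)
  rk <- stats::setNames(integer(length(feats)), feats)
  active <- feats
  pos <- length(feats)
  yy <- as.numeric(y == levels(y)[2])
  while (length(active) > 1) {
    fit <- suppressWarnings(
      stats::glm(yy ~ ., data = data.frame(X[, active, drop = FALSE]),
                 family = stats::binomial()))
    co <- stats::coef(fit)[-1]
    co[is.na(co)] <- 0
    worst <- active[which.min(abs(co))]
    rk[worst] <- pos
    pos <- pos - 1L
    active <- setdiff(active, worst)
  }
  rk[active] <- 1L
  unname(rk[feats])
}

#' Multi-selector feature ranking with a redundancy-weighted score
#'
#' Five selectors rank all features: bagged-tree impurity importance,
#' extremely-randomized-tree impurity importance, univariate F score,
#' univariate mutual information, and recursive feature elimination with a
#' linear classifier. Each feature's redundancy-weighted score is
#' `mean_rank + w * rank_sd`, penalising both poor and unstable ranks;
#' final order is ascending in that score (ties by mean rank, then name).
#' Features are min-max scaled internally.
#'
#' @param cohort A `cohort_table` (must contain `group`).
#' @param features Feature names (>= 2).
#' @param seed Integer seed controlling the stochastic selectors.
#' @param sd_weight Weight `w` on the rank SD (default 1).
#' @return Data frame (class `rank_table`): per feature the five selector
#'   ranks, `mean_rank`, `rank_sd`, `redundancy_score` and `final_rank`.
#' @export
rank_features <- function(cohort, features, seed = 1, sd_weight = 1) {
  if (length(features) < 2)
    stop("rank_features: need at least 2 features")
  Xdf <- minmax_scale(cohort, features)
  features <- names(Xdf)
  X <- as.matrix(Xdf)
  y <- factor(cohort$group)
  sel <- list(bagged_trees = selector_bagged_trees,
              extra_trees = selector_extra_trees,
              f_score = selector_f_score,
              mutual_info = selector_mutual_info,
              rfe_linear = selector_rfe_linear)
  ranks <- vapply(sel, function(f) f(X, y, seed), integer(length(features)))
  mean_rank <- rowMeans(ranks)
  rank_sd <- apply(ranks, 1, stats::sd)
  score <- mean_rank + sd_weight * rank_sd
  out <- data.frame(feature = features, ranks, mean_rank = mean_rank,
                    rank_sd = rank_sd, redundancy_score = score)
  out <- out[order(score, mean_rank, features), ]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Gamma separability ranking
#'
#' Univariate between-group discriminability
#' `gamma = |mu1 - mu2| / sqrt(sd1^2 + sd2^2)` per feature, in descending
#' order.
#'
#' @param cohort A `cohort_table`.
#' @param features Feature names.
#' @return Data frame `feature`, `gamma`, sorted descending.
#' @export
gamma_rank <- function(cohort, features) {
  g <- factor(cohort$group)
  stopifnot(nlevels(g) == 2, min(table(g)) >= 3)
  gam <- vapply(features, function(v) {
    x <- cohort[[v]]
    x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
    denom <- sqrt(stats::var(x1, na.rm = TRUE) + stats::var(x2, na.rm = TRUE))
    num <- abs(mean(x1, na.rm = TRUE) - mean(x2, na.rm = TRUE))
    if (denom == 0) {
      if (num > 0) {
        warning("gamma_rank: zero dispersion with group separation for ", v)
        return(Inf)
      }
      return(0)
    }
    num / denom
  }, numeric(1))
  out <- data.frame(feature = features, gamma = gam)
  out <- out[order(-gam, features), ]
  rownames(out) <- NULL
  out
}

#' Select the final top features from the two rankings
#'
#' Features present in the top-`n_top` of both the redundancy-weighted rank
#' table and the gamma ranking enter first; remaining slots are filled by
#' the arbiter policy: `"redundancy"` (default, fill by redundancy score),
#' `"gamma"`, or a character vector of manual picks (an expert-override
#' hook).
#'
#' @param rank_table Output of [rank_features()].
#' @param gamma_table Output of [gamma_rank()].
#' @param n_top Number of features to select (default 5).
#' @param arbiter `"redundancy"`, `"gamma"`, or character vector of feature
#'   names used (in order) to fill the remaining slots.
#' @return List: `selected` (character, length `n_top`), `automatic`
#'   (the consensus features), `arbitrated` (features added by the arbiter).
#' @export
select_top <- function(rank_table, gamma_table, n_top = 5,
                       arbiter = "redundancy") {
  if (n_top > nrow(rank_table))
    stop("select_top: n_top exceeds number of ranked features")
  top_r <- rank_table$feature[seq_len(n_top)]
  top_g <- gamma_table$feature[seq_len(min(n_top, nrow(gamma_table)))]
  auto <- intersect(top_r, top_g)
  auto <- top_r[top_r %in% auto]  # keep redundancy order
  pool <- if (identical(arbiter, "redundancy")) {
    setdiff(rank_table$feature, auto)
  } else if (identical(arbiter, "gamma")) {
    setdiff(gamma_table$feature, auto)
  } else {
    c(setdiff(arbiter, auto), setdiff(rank_table$feature, c(auto, arbiter)))
  }
  fill <- utils::head(pool, n_top - length(auto))
  list(selected = c(auto, fill), automatic = auto, arbitrated = fill)
}
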