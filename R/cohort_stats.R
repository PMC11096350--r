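# Descriptive statistics for the two-group, two-position cohort.

# Shapiro-Wilk gate; returns TRUE when the sample is compatible with
# normality (p >= alpha). Constant samples fail the gate conservatively.
passes_normality <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk on each group; if both are compatible with normality a
#' Welch two-sample t-test is used, otherwise a Mann-Whitney U
#' (Wilcoxon rank-sum) test. The chosen test is returned transparently.
#'
#' @param cohort A `cohort_table` (or any data.frame with a `group` column).
#' @param variable Name of the numeric column to compare.
#' @param alpha_normality Shapiro-Wilk gate level (default 0.05).
#' @return List: `variable`, `test_name`, `statistic`, `df` (or `NA`),
#'   `p_unadjusted`, `p_adjusted` (equal to unadjusted here),
#'   `significant_05`, `significant_10`.
#' @export
univariate_compare <- function(cohort, variable, alpha_normality = 0.05) {
  g <- factor(cohort$group)
  if (nlevels(g) != 2) stop("univariate_compare: need exactly two groups")
  x <- cohort[[variable]]
  if (is.null(x)) stop("univariate_compare: unknown variable ", variable)
  x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
  x1 <- x1[is.finite(x1)]; x2 <- x2[is.finite(x2)]
  if (length(x1) < 3 || length(x2) < 3)
    stop("univariate_compare: need >= 3 observations per group")
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0)
    stop("univariate_compare: zero variance in both groups for ", variable)
  if (passes_normality(x1, alpha_normality) &&
      passes_normality(x2, alpha_normality)) {
    tt <- stats::t.test(x1, x2)
    res <- list(test_name = "welch_t", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_unadjusted = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = FALSE))
    res <- list(test_name = "mann_whitney",
                statistic = unname(wt$statistic),
                df = NA_real_, p_unadjusted = wt$p.value)
  }
  c(list(variable = variable), res,
    list(p_adjusted = res$p_unadjusted,
         significant_05 = res$p_unadjusted < 0.05,
         significant_10 = res$p_unadjusted < 0.10))
}

#' Categorical two-group comparison
#'
#' Fisher's exact test when any expected cell count is 5 or fewer (for 2x2
#' tables), otherwise a chi-square test.
#'
#' @param tab A 2 x k matrix of non-negative integer counts.
#' @return List with `test_name`, `statistic` (NA for Fisher), `df`,
#'   `p_unadjusted`.
#' @export
categorical_compare <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("categorical_compare: counts must be non-negative integers")
  if (sum(tab) == 0) stop("categorical_compare: all-zero table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(dim(tab) == c(2, 2)) && any(expected <= 5)) {
    ft <- stats::fisher.test(tab)
    list(test_name = "fisher_exact", statistic = NA_real_, df = NA_real_,
         p_unadjusted = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(test_name = "chi_square", statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_unadjusted = ct$p.value)
  }
}

# Scheirer-Ray-Hare rank-based two-way factorial: ranks the pooled response,
# runs a two-way ANOVA on the ranks, and converts each effect sum of
# squares to an H statistic via the total mean square; H ~ chi-square.
scheirer_ray_hare <- function(value, group, position) {
  rk <- rank(value)
  fit <- stats::aov(rk ~ group * position)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  df <- summary(fit)[[1]][["Df"]]
  ms_total <- sum((rk - mean(rk))^2) / (length(rk) - 1)
  eff <- c("clinical_form", "position", "interaction")
  out <- lapply(1:3, function(i) {
    H <- ss[i] / ms_total
    list(effect = eff[i], statistic = H, df = df[i],
         p = stats::pchisq(H, df[i], lower.tail = FALSE))
  })
  names(out) <- eff
  out
}

#' Two-way mixed (split-plot) ANOVA with rank-based fallback
#'
#' Between-subject factor: clinical form; within-subject factor: position
#' (each subject contributes the S1 and S2 value of the variable). When the
#' residuals of the cell-means fit fail Shapiro-Wilk normality
#' (p < 0.05), a Scheirer-Ray-Hare rank-based factorial is used instead,
#' yielding H statistics. P-values are Bonferroni-adjusted by 3 (the three
#' effects tested per variable), capped at 1.
#'
#' @param cohort A `cohort_table` with `{variable}_S1` / `{variable}_S2`
#'   columns and a `group` column.
#' @param variable Base metric name (e.g. `"mean_HR"`).
#' @param bonferroni_k Multiplicity factor (default 3).
#' @return Data frame with one row per effect (`clinical_form`, `position`,
#'   `interaction`): `statistic_type` (F or H), `statistic`, `df`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
mixed_anova <- function(cohort, variable, bonferroni_k = 3) {
  v1 <- cohort[[paste0(variable, "_S1")]]
  v2 <- cohort[[paste0(variable, "_S2")]]
  if (is.null(v1) || is.null(v2))
    stop("mixed_anova: columns for variable ", variable, " not found")
  ok <- is.finite(v1) & is.finite(v2)
  if (sum(!ok)) warning("mixed_anova: excluding ", sum(!ok),
                        " subject(s) with missing values")
  v1 <- v1[ok]; v2 <- v2[ok]
  grp <- factor(cohort$group[ok])
  if (min(table(grp)) < 3)
    stop("mixed_anova: need >= 3 subjects per group")
  n <- length(v1)
  long <- data.frame(
    value = c(v1, v2),
    group = factor(rep(grp, 2)),
    position = factor(rep(c("S1", "S2"), each = n)),
    subject = factor(rep(seq_len(n), 2)))
  resid_fit <- stats::lm(value ~ group * position, data = long)
  normal_ok <- passes_normality(stats::residuals(resid_fit))
  eff <- c("clinical_form", "position", "interaction")
  if (normal_ok) {
    fit <- stats::aov(value ~ group * position + Error(subject),
                      data = long)
    sm <- summary(fit)
    between <- sm[["Error: subject"]][[1]]
    within <- sm[["Error: Within"]][[1]]
    rows <- data.frame(
      effect = eff,
      statistic_type = "F",
      statistic = c(between[["F value"]][1], within[["F value"]][1:2]),
      df = c(between[["Df"]][1], within[["Df"]][1:2]),
      p_unadjusted = c(between[["Pr(>F)"]][1], within[["Pr(>F)"]][1:2]))
  } else {
    srh <- scheirer_ray_hare(long$value, long$group, long$position)
    rows <- data.frame(
      effect = eff,
      statistic_type = "H",
      statistic = vapply(srh, `[[`, numeric(1), "statistic"),
      df = vapply(srh, `[[`, numeric(1), "df"),
      p_unadjusted = vapply(srh, `[[`, numeric(1), "p"))
  }
  rows$p_adjusted <- pmin(1, rows$p_unadjusted * bonferroni_k)
  rows$variable <- variable
  rownames(rows) <- NULL
  rows
}

#' Pairwise correlation matrix with significance masking
#'
#' Pearson correlation when both variables pass Shapiro-Wilk normality,
#' Spearman otherwise. Entries whose correlation test p-value is >= 0.05
#' are masked to `NA` in `R_masked`.
#'
#' @param cohort Data frame.
#' @param variables Character vector of column names (>= 2).
#' @return List of matrices `R`, `p`, `R_masked` and character matrix
#'   `method`.
#' @export
correlation_matrix <- function(cohort, variables) {
  k <- length(variables)
  stopifnot(k >= 2)
  R <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  method <- matrix(NA_character_, k, k, dimnames = list(variables, variables))
  normal <- vapply(variables, function(v) passes_normality(cohort[[v]]),
                   logical(1))
  for (i in seq_len(k)) {
    R[i, i] <- 1; p[i, i] <- 0; method[i, i] <- "pearson"
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- cohort[[variables[i]]]; y <- cohort[[variables[j]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 4 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning("correlation_matrix: degenerate pair ",
                variables[i], " / ", variables[j])
        next
      }
      meth <- if (normal[i] && normal[j]) "pearson" else "spearman"
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = meth, exact = FALSE))
      R[i, j] <- R[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      method[i, j] <- method[j, i] <- meth
    }
  }
  R_masked <- R
  R_masked[!is.na(p) & p >= 0.05] <- NA_real_
  diag(R_masked) <- 1
  list(R = R, p = p, R_masked = R_masked, method = method)
}

#' Group x position summary of the cohort
#'
#' Mean and SD of every registry metric per group and position, the three
#' mixed-ANOVA effect p-values, and the two-group comparison of the
#' stand-up deltas.
#'
#' @param cohort A `cohort_table`.
#' @return Data frame, one row per registry metric.
#' @export
cohort_summary_table <- function(cohort) {
  reg <- names(hrv_metric_registry())
  g <- factor(cohort$group)
  lv <- levels(g)
  rows <- lapply(reg, function(v) {
    an <- tryCatch(mixed_anova(cohort, v), error = function(e) NULL)
    dl <- tryCatch(univariate_compare(cohort, paste0(v, "_delta")),
                   error = function(e) NULL)
    cell <- function(col, grp) {
      x <- cohort[[col]][g == grp]
      sprintf("%.3g ± %.3g", mean(x, na.rm = TRUE),
              stats::sd(x, na.rm = TRUE))
    }
    data.frame(
      metric = v,
      dcSSc_S1 = cell(paste0(v, "_S1"), lv[1]),
      lcSSc_S1 = cell(paste0(v, "_S1"), lv[2]),
      dcSSc_S2 = cell(paste0(v, "_S2"), lv[1]),
      lcSSc_S2 = cell(paste0(v, "_S2"), lv[2]),
      p_clinical_form = if (is.null(an)) NA else an$p_adjusted[1],
      p_position = if (is.null(an)) NA else an$p_adjusted[2],
      p_interaction = if (is.null(an)) NA else an$p_adjusted[3],
      dcSSc_delta = cell(paste0(v, "_delta"), lv[1]),
      lcSSc_delta = cell(paste0(v, "_delta"), lv[2]),
      p_delta = if (is.null(dl)) NA else dl$p_unadjusted)
  })
  do.call(rbind, rows)
}
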