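# Cohort assembly: per-subject S1/S2 metric vectors and stand-up deltas.

#' The fixed HRV metric registry
#'
#' The 29 metrics extracted per 5-min segment: 7 time-domain, 10
#' frequency-domain and 12 nonlinear-domain. Degenerate or strictly
#' redundant recurrence statistics (Lmin, which is the configured minimum
#' line length by construction, and DIV = 1/Lmax) and the SD1/SD2 ratio are
#' reported by their own operations but excluded from the cohort feature
#' registry.
#'
#' @return Named character vector mapping metric name to domain.
#' @export
hrv_metric_registry <- function() {
  c(mean_RR = "time", sd_RR = "time", mean_HR = "time", sd_HR = "time",
    RMSSD = "time", NN50 = "time", pNN50 = "time",
    LF_peak = "freq", HF_peak = "freq", LF_power = "freq",
    LF_power_prc = "freq", LF_power_nu = "freq", HF_power = "freq",
    HF_power_prc = "freq", HF_power_nu = "freq", LF_HF_power = "freq",
    tot_power = "freq",
    SD1 = "nonlinear", SD2 = "nonlinear", ApEn = "nonlinear",
    SampEn = "nonlinear", alpha1 = "nonlinear", alpha2 = "nonlinear",
    CorDim = "nonlinear", Lmax = "nonlinear", Lmean = "nonlinear",
    REC = "nonlinear", DET = "nonlinear", ShanEn = "nonlinear")
}

#' All registry metrics for one RR segment
#'
#' Runs the time-, frequency- and nonlinear-domain extraction on one
#' corrected segment and returns the 29 registry metrics in registry order.
#'
#' @param rri An [rri_series()] (a corrected ~5-min segment).
#' @return Named numeric vector of length 29 (class `hrv_vector`).
#' @export
hrv_vector <- function(rri) {
  td <- time_domain_metrics(rri)
  fd <- freq_domain_metrics(rri)
  nl <- nonlinear_metrics(rri)
  all <- c(td, fd, nl)
  reg <- names(hrv_metric_registry())
  out <- vapply(reg, function(nm) as.numeric(all[[nm]]), numeric(1))
  class(out) <- c("hrv_vector", "numeric")
  out
}

#' Metric vectors and stand-up deltas for one subject
#'
#' Extracts the full metric set on the decubitus (S1) and orthostatism (S2)
#' segments and their difference `delta = S2 - S1`, after artifact
#' correction of each segment.
#'
#' @param s1,s2 [rri_series()] for the two positions.
#' @param correct Apply [correct_artifacts()] to each segment first
#'   (default `TRUE`).
#' @return List with `S1`, `S2`, `delta` (each an `hrv_vector`) and
#'   `correction_reports`.
#' @export
stand_up_features <- function(s1, s2, correct = TRUE) {
  reports <- list()
  if (correct) {
    c1 <- tryCatch(correct_artifacts(s1),
                   error = function(e) stop("S1 segment: ",
                                            conditionMessage(e)))
    c2 <- tryCatch(correct_artifacts(s2),
                   error = function(e) stop("S2 segment: ",
                                            conditionMessage(e)))
    s1 <- c1$rri; s2 <- c2$rri
    reports <- list(S1 = c1$report, S2 = c2$report)
  }
  v1 <- tryCatch(hrv_vector(s1),
                 error = function(e) stop("S1 segment: ",
                                          conditionMessage(e)))
  v2 <- tryCatch(hrv_vector(s2),
                 error = function(e) stop("S2 segment: ",
                                          conditionMessage(e)))
  d <- v2 - v1
  class(d) <- class(v1)
  list(S1 = v1, S2 = v2, delta = d, correction_reports = reports)
}

#' Build the cohort feature table
#'
#' One row per subject with the 87 features `{metric}_{S1|S2|delta}` plus
#' the group label. Subjects whose files are unreadable or whose segments
#' fail the artifact-correction quality gate are excluded and listed in the
#' exclusion report.
#'
#' @param manifest A `cohort_manifest` (see [read_cohort_manifest()]).
#' @param correct Apply artifact correction per segment (default `TRUE`).
#' @param qrs_cfg A [qrs_config()] used when `input_kind == "ecg"`.
#' @return List with `table` (data.frame of class `cohort_table`, 88
#'   columns) and `exclusions` (data.frame `subject_id`, `reason`).
#' @export
build_cohort <- function(manifest, correct = TRUE, qrs_cfg = qrs_config()) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  reg <- names(hrv_metric_registry())
  cols <- c(paste0(reg, "_S1"), paste0(reg, "_S2"), paste0(reg, "_delta"))
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      load_seg <- function(path) {
        if (row$input_kind == "ecg") {
          df <- utils::read.csv(path)
          fs <- 1 / stats::median(diff(df[[1]]))
          ecg_to_rri(sampled_signal(df[[2]], fs = fs), qrs_cfg)
        } else read_rri(path)
      }
      s1 <- load_seg(row$path_S1)
      s2 <- load_seg(row$path_S2)
      stand_up_features(s1, s2, correct = correct)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <-
        data.frame(subject_id = row$subject_id,
                   reason = conditionMessage(res))
      next
    }
    vals <- c(res$S1, res$S2, res$delta)
    df <- as.data.frame(as.list(stats::setNames(as.numeric(vals), cols)))
    df$subject_id <- row$subject_id
    df$group <- row$group
    rows[[length(rows) + 1L]] <- df
  }
  if (length(rows) == 0L)
    stop("build_cohort: no subjects survived the quality gates")
  tab <- do.call(rbind, rows)
  rownames(tab) <- tab$subject_id
  tab$subject_id <- NULL
  tab <- tab[, c(cols, "group")]
  class(tab) <- c("cohort_table", "data.frame")
  list(table = tab,
       exclusions = if (length(excl)) do.call(rbind, excl)
                    else data.frame(subject_id = character(0),
                                    reason = character(0)))
}
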