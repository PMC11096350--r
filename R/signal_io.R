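#' Construct a uniformly sampled signal
#'
#' Container for a uniformly sampled waveform: raw ECG amplitude (arbitrary
#' units) or a spline-resampled RR-interval tachogram (ms).
#'
#' @param values Numeric vector of sample values. Must be non-empty and free
#'   of `NA`/`NaN`.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return An object of class `sampled_signal` with elements `values`, `fs`,
#'   `start_time`.
#' @export
#' @examples
#' s <- sampled_signal(sin(seq(0, 10, by = 0.25)), fs = 4)
#' length(s$values)
sampled_signal <- function(values, fs, start_time = 0) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("sampled_signal: 'values' must be non-empty")
  if (anyNA(values)) stop("sampled_signal: 'values' contains NA/NaN")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("sampled_signal: 'fs' must be a single positive number")
  structure(list(values = values, fs = as.numeric(fs),
                 start_time = as.numeric(start_time)),
            class = "sampled_signal")
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d samples @ %g Hz (%.1f s)\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' Construct an RR-interval series
#'
#' Beat-to-beat RR intervals in milliseconds with per-beat occurrence times
#' in seconds and quality flags. Beat times and intervals are kept mutually
#' consistent: `beat_times[k] - beat_times[k-1] == intervals[k] / 1000`.
#'
#' @param intervals Numeric vector of RR intervals in ms (all > 0).
#' @param beat_times Optional numeric vector of beat occurrence times in
#'   seconds (strictly increasing, same length as `intervals`). When omitted,
#'   times are reconstructed as the cumulative sum of `intervals / 1000`.
#' @param flags Character vector of per-beat labels, each one of
#'   `"normal"`, `"ectopic"`, `"interpolated"`. Defaults to all `"normal"`.
#'
#' @return An object of class `rri_series` with elements `intervals`,
#'   `beat_times`, `flags`.
#' @export
#' @examples
#' r <- rri_series(c(1000, 1000, 1000))
#' r$beat_times  # 1, 2, 3
rri_series <- function(intervals, beat_times = NULL, flags = NULL) {
  intervals <- as.numeric(intervals)
  if (length(intervals) == 0L) stop("rri_series: empty interval vector")
  if (anyNA(intervals) || any(intervals <= 0))
    stop("rri_series: all intervals must be positive and non-missing")
  if (is.null(beat_times)) {
    beat_times <- cumsum(intervals) / 1000
  } else {
    beat_times <- as.numeric(beat_times)
    if (length(beat_times) != length(intervals))
      stop("rri_series: beat_times and intervals length mismatch")
    if (any(diff(beat_times) <= 0))
      stop("rri_series: beat_times must be strictly increasing")
    gaps <- diff(beat_times) - intervals[-1L] / 1000
    if (length(gaps) && max(abs(gaps)) > 1e-9)
      stop("rri_series: beat_times inconsistent with intervals")
  }
  if (is.null(flags)) flags <- rep("normal", length(intervals))
  flags <- as.character(flags)
  if (length(flags) != length(intervals))
    stop("rri_series: flags length mismatch")
  bad <- setdiff(unique(flags), c("normal", "ectopic", "interpolated"))
  if (length(bad))
    stop("rri_series: unknown flag value(s): ", paste(bad, collapse = ", "))
  structure(list(intervals = intervals, beat_times = beat_times,
                 flags = flags),
            class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series> %d beats, mean RR %.1f ms, span %.1f s\n",
              length(x$intervals), mean(x$intervals),
              diff(range(x$beat_times))))
  invisible(x)
}

#' Read an RR-interval series from disk
#'
#' Two plain-text dialects are supported. `plain_ms` is one interval in ms
#' per line; beat times are reconstructed by cumulative sum. `csv_times` is a
#' CSV with columns `beat_time_s`, `rr_ms` and optionally `flag`.
#'
#' @param path Path to an existing file.
#' @param dialect `"plain_ms"` (default) or `"csv_times"`.
#'
#' @return An [rri_series()].
#' @export
read_rri <- function(path, dialect = c("plain_ms", "csv_times")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_rri: file not found: ", path)
  if (dialect == "plain_ms") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("read_rri: empty file: ", path)
    vals <- suppressWarnings(as.numeric(lines))
    if (anyNA(vals))
      stop("read_rri: non-numeric interval on line ", which(is.na(vals))[1L],
           " of ", path)
    if (any(vals <= 0))
      stop("read_rri: non-positive interval on line ",
           which(vals <= 0)[1L], " of ", path)
    rri_series(vals)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("beat_time_s", "rr_ms")
    if (!all(need %in% names(df)))
      stop("read_rri: csv_times file must have columns ",
           paste(need, collapse = ", "))
    if (nrow(df) == 0L) stop("read_rri: empty file: ", path)
    if (anyNA(df$rr_ms) || !is.numeric(df$rr_ms))
      stop("read_rri: non-numeric interval on line ",
           which(is.na(df$rr_ms))[1L] + 1L, " of ", path)
    if (any(df$rr_ms <= 0))
      stop("read_rri: non-positive interval on line ",
           which(df$rr_ms <= 0)[1L] + 1L, " of ", path)
    flags <- if ("flag" %in% names(df)) df$flag else NULL
    rri_series(df$rr_ms, beat_times = df$beat_time_s, flags = flags)
  }
}

#' Write an RR-interval series to disk
#'
#' Fixed-point output with 3 decimal places, so read/write round-trips are
#' lossless at millisecond precision times 1e-3.
#'
#' @param series An [rri_series()].
#' @param path Output path.
#' @param dialect `"plain_ms"` or `"csv_times"` (see [read_rri()]).
#' @return Invisibly, `path`.
#' @export
write_rri <- function(series, path, dialect = c("plain_ms", "csv_times")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(series, "rri_series"))
  if (dialect == "plain_ms") {
    writeLines(sprintf("%.3f", series$intervals), con = path)
  } else {
    df <- data.frame(beat_time_s = sprintf("%.6f", series$beat_times),
                     rr_ms = sprintf("%.3f", series$intervals),
                     flag = series$flags)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and validate a cohort manifest
#'
#' The manifest maps each subject to a group label and the paths of the two
#' recording segments (S1 = decubitus, S2 = orthostatism). Group labels are
#' normalised case-insensitively to `dcSSc` / `lcSSc`.
#'
#' @param path CSV file with columns `subject_id`, `group`, `path_S1`,
#'   `path_S2` and optionally `input_kind` (`"rri"` default, or `"ecg"`).
#' @return A `data.frame` of class `cohort_manifest`.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("read_cohort_manifest: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path_S1", "path_S2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_cohort_manifest: missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"input_kind" %in% names(df)) df$input_kind <- "rri"
  dup <- unique(df$subject_id[duplicated(df$subject_id)])
  if (length(dup))
    stop("read_cohort_manifest: duplicated subject_id: ",
         paste(dup, collapse = ", "))
  grp <- normalize_group(df$group)
  if (anyNA(grp))
    stop("read_cohort_manifest: unknown group label(s): ",
         paste(unique(df$group[is.na(grp)]), collapse = ", "))
  df$group <- grp
  bad_kind <- setdiff(unique(df$input_kind), c("rri", "ecg"))
  if (length(bad_kind))
    stop("read_cohort_manifest: unknown input_kind: ",
         paste(bad_kind, collapse = ", "))
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

# Case-insensitive normalisation of clinical-form labels; NA when unknown.
normalize_group <- function(x) {
  out <- rep(NA_character_, length(x))
  lx <- tolower(trimws(x))
  out[lx == "dcssc"] <- "dcSSc"
  out[lx == "lcssc"] <- "lcSSc"
  out
}
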