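#' Daily count series
#'
#' The universal input type of the package: a contiguous, dated sequence of
#' daily counts.  Values are stored as doubles so that a jittered series
#' (integer counts plus uniform noise strictly inside (-0.5, 0.5)) can reuse
#' the same container; the `jittered` attribute records whether jitter has
#' been applied.  Un-jittered series must hold non-negative integers.
#'
#' @param dates `Date` vector, strictly increasing at daily resolution.
#' @param values numeric vector of the same length; non-negative integers
#'   unless `jittered = TRUE`, in which case each value must lie within 0.5
#'   of a non-negative integer (so values >= -0.5).
#' @param label free-text identifier carried through reports.
#' @param jittered has uniform jitter been applied?
#' @param allow_gaps permit missing calendar days.  Gapped series are
#'   accepted for storage but rejected by decomposition-based operations.
#'
#' @return An object of class `daily_count_series`.
#' @export
daily_count_series <- function(dates, values, label = "series",
                               jittered = FALSE, allow_gaps = FALSE) {
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  if (anyNA(dates)) {
    stop_shesd("dates contain NA or unparseable entries", "shesd_parse_error")
  }
  if (length(dates) != length(values)) {
    stop_shesd("dates and values differ in length", "shesd_parse_error")
  }
  if (length(dates) == 0) {
    stop_shesd("empty series", "shesd_empty_input_error")
  }
  d <- diff(as.integer(dates))
  if (any(d <= 0)) {
    dup <- dates[which(d <= 0)[1] + 1]
    stop_shesd(sprintf("dates not strictly increasing (at %s)", dup),
               "shesd_parse_error", date = dup)
  }
  has_gaps <- any(d > 1)
  if (has_gaps && !allow_gaps) {
    gap_at <- dates[which(d > 1)[1]]
    stop_shesd(sprintf("missing calendar days after %s", gap_at),
               "shesd_gap_error", date = gap_at)
  }
  values <- as.numeric(values)
  if (anyNA(values)) {
    stop_shesd("values contain NA", "shesd_parse_error")
  }
  if (jittered) {
    if (any(values < -0.5)) {
      stop_shesd("jittered values must be >= -0.5", "shesd_negative_count_error")
    }
  } else {
    if (any(values < 0)) {
      stop_shesd("counts must be non-negative", "shesd_negative_count_error")
    }
    if (!all(is_wholenumber(values))) {
      stop_shesd("un-jittered counts must be integers", "shesd_parse_error")
    }
  }
  structure(
    list(dates = dates, values = values, label = label),
    jittered = jittered, has_gaps = has_gaps,
    class = "daily_count_series"
  )
}

#' @export
length.daily_count_series <- function(x) length(x$values)

#' @export
as.data.frame.daily_count_series <- function(x, ...) {
  data.frame(date = x$dates, count = x$values)
}

#' @export
print.daily_count_series <- function(x, ...) {
  cat(sprintf(
    "<daily_count_series '%s': %d days, %s .. %s%s%s>\n",
    x$label, length(x), format(x$dates[1]), format(x$dates[length(x)]),
    if (isTRUE(attr(x, "jittered"))) ", jittered" else "",
    if (isTRUE(attr(x, "has_gaps"))) ", gapped" else ""
  ))
  cat(sprintf("  mean %.2f, sd %.2f, range [%g, %g]\n",
              mean(x$values), stats::sd(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

is_jittered <- function(series) isTRUE(attr(series, "jittered"))

#' Read a daily count series from a two-column delimited file
#'
#' Expects a header line `date,count` (any names accepted), ISO-8601 dates
#' in the first column and numeric counts in the second.  Rows are ordered
#' by date; duplicate dates and calendar gaps are rejected.
#'
#' @param path file path.
#' @param sep field delimiter (default comma).
#' @param label series label; defaults to the file base name.
#' @param allow_gaps permit missing calendar days.
#' @return A [daily_count_series()].
#' @export
read_series <- function(path, sep = ",", label = NULL, allow_gaps = FALSE) {
  if (!file.exists(path)) {
    stop_shesd(sprintf("file not found: %s", path), "shesd_parse_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           strip.white = TRUE)
  if (ncol(raw) < 2) {
    stop_shesd("expected two columns (date, count)", "shesd_parse_error")
  }
  dates <- as.Date(raw[[1]], format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad)) {
    stop_shesd(sprintf("row %d: unparseable date '%s'", bad[1], raw[[1]][bad[1]]),
               "shesd_parse_error", row = bad[1])
  }
  values <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(values))
  if (length(bad)) {
    stop_shesd(sprintf("row %d: unparseable count '%s'", bad[1], raw[[2]][bad[1]]),
               "shesd_parse_error", row = bad[1])
  }
  if (anyDuplicated(dates)) {
    dup <- dates[duplicated(dates)][1]
    stop_shesd(sprintf("duplicated date %s", dup), "shesd_parse_error",
               date = dup)
  }
  o <- order(dates)
  daily_count_series(dates[o], values[o],
                     label = label %||% sub("\\.[^.]*$", "", basename(path)),
                     allow_gaps = allow_gaps)
}

#' Write a daily count series as two-column CSV
#'
#' @param series a [daily_count_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Inclusive span between two calendar dates, in days
#'
#' Gregorian and leap-aware: `date_span_days("1996-07-01", "2009-06-30")`
#' is 4748, the length of a 13-year daily series over that window.
#'
#' @param start,end `Date` (or coercible); `start` must not follow `end`.
#' @return integer count of calendar days, both endpoints included.
#' @export
date_span_days <- function(start, end) {
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end)) {
    stop_shesd("unparseable date", "shesd_parse_error")
  }
  if (start > end) {
    stop_shesd("start date is after end date", "shesd_order_error")
  }
  as.integer(end - start) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
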