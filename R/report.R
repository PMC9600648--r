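# Common AnomalyReport container shared by all three detectors, so the
# evaluation module is detector-agnostic.

#' Construct an anomaly report
#'
#' @param records data.frame with columns `date`, `observed`, `residual`,
#'   `statistic`, `critical_value`, `rank`, `flagged` (logical) and
#'   `significant` (logical, `NA` for detectors without a formal test).
#'   For the ESD detector the records hold every tested candidate in
#'   removal order; for threshold detectors only the flagged days.
#' @param method detector tag (`"shesd"`, `"tmqq"`, `"m4sd"`).
#' @param alpha nominal significance level, `NA` for threshold detectors.
#' @param k_used number of outliers declared by the ESD decision rule.
#' @param jitter_applied was the series jittered before detection?
#' @param date_range `Date` vector of length 2, the span of the analysed
#'   series (used for range checks when scoring).
#' @param extra named list of method-specific metadata.
#' @return An object of class `anomaly_report`.
#' @keywords internal
anomaly_report <- function(records, method, alpha = NA_real_,
                           k_used = NA_integer_, jitter_applied = FALSE,
                           date_range = NULL, extra = list()) {
  records <- records[order(records$rank), , drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(records = records, method = method, alpha = alpha,
         k_used = k_used, jitter_applied = jitter_applied,
         date_range = date_range, extra = extra),
    class = "anomaly_report"
  )
}

#' Dates flagged as anomalous by a detector
#'
#' @param report an `anomaly_report`.
#' @return Sorted `Date` vector of flagged days.
#' @export
flagged_dates <- function(report) {
  sort(report$records$date[report$records$flagged])
}

#' @export
print.anomaly_report <- function(x, ...) {
  nf <- sum(x$records$flagged)
  cat(sprintf("<anomaly_report [%s]: %d day(s) flagged%s%s>\n",
              x$method, nf,
              if (!is.na(x$alpha)) sprintf(", alpha %.3g", x$alpha) else "",
              if (isTRUE(x$jitter_applied)) ", jitter applied" else ""))
  if (nf > 0) {
    f <- x$records[x$records$flagged, c("date", "observed", "statistic"), drop = FALSE]
    f <- f[order(f$date), ]
    rownames(f) <- NULL
    print(utils::head(f, 25))
    if (nf > 25) cat(sprintf("  ... and %d more\n", nf - 25))
  }
  invisible(x)
}

#' @export
as.data.frame.anomaly_report <- function(x, ...) x$records

#' Write an anomaly report as CSV
#'
#' Emits `date,count,statistic,critical_value,rank,method,significance`;
#' `significance` is `TRUE`/`FALSE` for the ESD detector and `NA` for the
#' threshold comparators, which attach no formal test.
#'
#' @param report an `anomaly_report`.
#' @param path output path.
#' @param flagged_only drop non-flagged candidate rows (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, flagged_only = TRUE) {
  r <- report$records
  if (flagged_only) r <- r[r$flagged, , drop = FALSE]
  out <- data.frame(date = r$date, count = r$observed,
                    statistic = r$statistic,
                    critical_value = r$critical_value, rank = r$rank,
                    method = report$method, significance = r$significant)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
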