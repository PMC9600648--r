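#' Robust seasonal-trend decomposition of a daily count series
#'
#' First stage of S-H-ESD: splits the series additively into seasonal,
#' trend and remainder components using STL (seasonal-trend decomposition
#' by loess).  With `robust = TRUE` the loess fits are iteratively
#' reweighted with bisquare weights on the remainder, so single large
#' spikes barely perturb the seasonal and trend estimates and survive into
#' the remainder, where the outlier test can see them.
#'
#' A fixed integer period (default 365) is kept over multi-year series by
#' removing February 29 observations before decomposition.  Leap days are
#' re-inserted afterwards with seasonal and remainder values linearly
#' interpolated from the neighbouring days, and trend defined as
#' `observed - seasonal - remainder` so the additive identity holds on
#' every day.  A leap day can therefore never itself be flagged; over a
#' 13-year series this affects at most 4 of 4748 days.
#'
#' @param series a gap-free [daily_count_series()] of length at least
#'   `2 * period`.
#' @param period seasonal period in days (default 365, annual seasonality).
#' @param robust use bisquare reweighting (default `TRUE`).
#' @param seasonal_window `"periodic"` for a strictly periodic seasonal
#'   component, or an odd integer loess span in cycles.
#' @return An object of class `stl_decomposition`: a list with `dates`,
#'   `observed`, `seasonal`, `trend`, `remainder` (all aligned with the
#'   input), `period` and `method_tag`.
#' @export
stl_decompose <- function(series, period = 365L, robust = TRUE,
                          seasonal_window = "periodic") {
  if (isTRUE(attr(series, "has_gaps"))) {
    stop_shesd("series has calendar gaps; decomposition needs a contiguous series",
               "shesd_gap_error")
  }
  n <- length(series)
  if (n <= 2 * period) {
    stop_shesd(sprintf("series length %d must exceed 2 x period %d", n,
                       period),
               "shesd_short_series_error")
  }
  x <- series$values
  leap <- format(series$dates, "%m-%d") == "02-29" & period == 365L
  y <- stats::ts(x[!leap], frequency = period)
  s_win <- if (identical(seasonal_window, "periodic")) "periodic"
           else as.numeric(seasonal_window)
  fit <- stats::stl(y, s.window = s_win, robust = robust)
  comp <- fit$time.series

  pos <- seq_len(n)
  interp <- function(v) stats::approx(pos[!leap], v, xout = pos, rule = 2)$y
  seasonal <- interp(as.numeric(comp[, "seasonal"]))
  remainder <- interp(as.numeric(comp[, "remainder"]))
  trend <- numeric(n)
  trend[!leap] <- as.numeric(comp[, "trend"])
  trend[leap] <- x[leap] - seasonal[leap] - remainder[leap]
  # on regular days the three stl components reconstruct x exactly
  remainder[!leap] <- x[!leap] - seasonal[!leap] - trend[!leap]

  structure(
    list(dates = series$dates, observed = x, seasonal = seasonal,
         trend = trend, remainder = remainder, period = as.integer(period),
         method_tag = sprintf("stl(s.window=%s, robust=%s)",
                              paste(seasonal_window, collapse = ""), robust)),
    class = "stl_decomposition"
  )
}

#' @export
print.stl_decomposition <- function(x, ...) {
  cat(sprintf("<stl_decomposition: %d days, period %d, %s>\n",
              length(x$observed), x$period, x$method_tag))
  cat(sprintf("  remainder sd %.3f, scaled MAD %.3f\n",
              stats::sd(x$remainder), robust_scale(x$remainder)$scale))
  invisible(x)
}

#' @export
as.data.frame.stl_decomposition <- function(x, ...) {
  data.frame(date = x$dates, observed = x$observed, seasonal = x$seasonal,
             trend = x$trend, remainder = x$remainder)
}

#' Residuals for outlier testing
#'
#' `mode = "remainder"` returns the STL remainder
#' (`observed - seasonal - trend`), the default residual passed to the
#' robust ESD test.  `mode = "seasonal_minus_median"` returns
#' `observed - seasonal - median(observed)`, the variant used by the
#' originating S-H-ESD software, which replaces the trend component with
#' the series median.
#'
#' @param series the decomposed [daily_count_series()].
#' @param result the matching [stl_decompose()] output.
#' @param mode `"remainder"` or `"seasonal_minus_median"`.
#' @return Numeric vector aligned with the series dates.
#' @export
extract_residuals <- function(series, result,
                              mode = c("remainder", "seasonal_minus_median")) {
  mode <- match.arg(mode)
  if (length(series) != length(result$observed) ||
      !all(series$dates == result$dates)) {
    stop_shesd("decomposition is not aligned with the series",
               "shesd_alignment_error")
  }
  if (mode == "remainder") {
    series$values - result$seasonal - result$trend
  } else {
    series$values - result$seasonal - stats::median(series$values)
  }
}

#' Dump a decomposition as five-column CSV
#'
#' Writes `date,observed,seasonal,trend,remainder` for plotting/debugging.
#'
#' @param result an [stl_decompose()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
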