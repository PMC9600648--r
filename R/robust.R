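#' Robust location and scale: median and scaled MAD
#'
#' Returns the median together with the scaled median absolute deviation,
#' the robust location/dispersion pair that replaces the sample mean and SD
#' inside the S-H-ESD test.  The scale is `constant * median(|x - median|)`;
#' the default constant 1.4826 makes the MAD a consistent estimator of the
#' standard deviation under normality.  The scale is exactly zero whenever
#' more than half of the values coincide with the median — the breakdown
#' mode of low-count discrete series that motivates the jitter extension.
#'
#' @param values non-empty numeric vector.
#' @param constant consistency constant (default 1.4826).
#' @return A list of class `robust_scale` with elements `center`, `scale`
#'   and `constant`.
#' @seealso [jitter_series()] for the zero-MAD remedy.
#' @export
robust_scale <- function(values, constant = 1.4826) {
  if (length(values) == 0 || all(is.na(values))) {
    stop_shesd("empty input", "shesd_empty_input_error")
  }
  center <- stats::median(values)
  scale <- constant * stats::median(abs(values - center))
  structure(list(center = center, scale = scale, constant = constant),
            class = "robust_scale")
}

#' @export
print.robust_scale <- function(x, ...) {
  cat(sprintf("<robust_scale: center %.4g, scale %.4g (constant %.4f)>\n",
              x$center, x$scale, x$constant))
  invisible(x)
}

#' Symmetrically trimmed mean and standard deviation
#'
#' Drops the `floor(trim_fraction * n)` smallest and largest values and
#' returns the mean and sample SD of the remainder.  With
#' `trim_fraction = 0.25` only the middle ~50% of the data contribute, the
#' convention of the rolling trimmed-mean comparator.
#'
#' @param values numeric vector.
#' @param trim_fraction fraction in `[0, 0.5)` removed from each tail.
#' @return Named numeric vector `c(mean = , sd = )`.
#' @export
trimmed_mean_sd <- function(values, trim_fraction = 0.25) {
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop_shesd("trim_fraction must lie in [0, 0.5)", "shesd_domain_error")
  }
  n <- length(values)
  k <- floor(trim_fraction * n)
  if (n - 2 * k < 2) {
    stop_shesd(sprintf("only %d value(s) remain after trimming", n - 2 * k),
               "shesd_degenerate_error")
  }
  kept <- sort(values)[(k + 1):(n - k)]
  c(mean = mean(kept), sd = stats::sd(kept))
}

#' Rolling trimmed mean and SD over a centred window
#'
#' Computes [trimmed_mean_sd()] in a centred window of odd width around
#' every day.  At the series edges the window shrinks rather than the day
#' being dropped, so every day remains classifiable; an edge window never
#' holds fewer than `ceiling(window / 2)` points.
#'
#' @param series a [daily_count_series()].
#' @param window odd window width in days, at most the series length.
#' @param trim_fraction passed to [trimmed_mean_sd()].
#' @return `data.frame(date, mean, sd)` aligned with the series.
#' @export
rolling_stat <- function(series, window, trim_fraction = 0.25) {
  n <- length(series)
  if (window %% 2 == 0 || window < 3 || window > n) {
    stop_shesd("window must be odd, >= 3 and <= series length",
               "shesd_window_error")
  }
  h <- (window - 1L) %/% 2L
  x <- series$values
  out <- vapply(seq_len(n), function(t) {
    w <- x[max(1L, t - h):min(n, t + h)]
    trimmed_mean_sd(w, trim_fraction)
  }, numeric(2))
  data.frame(date = series$dates, mean = out[1, ], sd = out[2, ])
}
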