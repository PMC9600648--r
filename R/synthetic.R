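# Synthetic admissions/readmissions generator.  Counts are drawn
# independently per day from a negative-binomial (or Poisson limit) with
# mean  base_level x seasonal(doy) x dow(weekday) x trend(date).
# The default specs are calibrated to the published summary statistics of
# the 13-year Victorian paediatric asthma series (admissions: mean 11.3,
# SD 6.0, range 0-51, late-summer/autumn peaks, declining-then-flat trend;
# readmissions: mean 0.5, SD 0.7, range 0-5, zero-dominated, winter peaks,
# declining-then-rising trend); the real series is access-restricted, so
# the generator is a structural stand-in, not a fit to the data.

#' Specification of a synthetic daily count series
#'
#' @param start_date,end_date series span (defaults give 4748 days, the
#'   length of the study window 1996-07-01 .. 2009-06-30).
#' @param base_level overall mean level (counts/day) before multipliers.
#' @param harmonics data.frame with columns `amp`, `order`, `phase_day`:
#'   each row contributes `amp * cos(2*pi*order*(doy - phase_day)/365.25)`
#'   on the log scale.
#' @param school_pulse optional list `(amp, center, width)`: a Gaussian
#'   log-scale pulse in day-of-year (e.g. a February return-to-school
#'   bump), or `NULL`.
#' @param dow_multipliers named numeric of length 7 (`Mon` .. `Sun`),
#'   multiplicative day-of-week effects.
#' @param trend_knots data.frame with columns `date`, `value`: long-term
#'   trend multiplier, linearly interpolated between knots.
#' @param dispersion negative-binomial size parameter; `Inf` for the
#'   Poisson limit.
#' @param seed default RNG seed for [generate_series()].
#' @param label series label.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(start_date = as.Date("1996-07-01"),
                           end_date = as.Date("2009-06-30"),
                           base_level = 10,
                           harmonics = data.frame(amp = numeric(),
                                                  order = integer(),
                                                  phase_day = numeric()),
                           school_pulse = NULL,
                           dow_multipliers = c(Mon = 1, Tue = 1, Wed = 1,
                                               Thu = 1, Fri = 1, Sat = 1,
                                               Sun = 1),
                           trend_knots = NULL,
                           dispersion = Inf, seed = 1996L,
                           label = "synthetic") {
  start_date <- as.Date(start_date); end_date <- as.Date(end_date)
  if (start_date > end_date) {
    stop_shesd("start_date after end_date", "shesd_order_error")
  }
  if (base_level < 0) {
    stop_shesd("base_level must be non-negative", "shesd_spec_error")
  }
  if (is.null(trend_knots)) {
    trend_knots <- data.frame(date = c(start_date, end_date), value = c(1, 1))
  }
  trend_knots$date <- as.Date(trend_knots$date)
  structure(
    list(start_date = start_date, end_date = end_date,
         base_level = base_level, harmonics = harmonics,
         school_pulse = school_pulse,
         dow_multipliers = dow_multipliers, trend_knots = trend_knots,
         dispersion = dispersion, seed = as.integer(seed), label = label),
    class = "synthetic_spec"
  )
}

#' Expected daily counts implied by a synthetic spec
#'
#' Deterministic mean curve `mu_t` (no noise), useful for calibration and
#' for checking that a spec never implies a negative expectation.
#'
#' @param spec a [synthetic_spec()].
#' @return `data.frame(date, mu)`.
#' @export
expected_counts <- function(spec) {
  dates <- seq(spec$start_date, spec$end_date, by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  log_seasonal <- rep(0, length(dates))
  h <- spec$harmonics
  for (j in seq_len(nrow(h))) {
    log_seasonal <- log_seasonal +
      h$amp[j] * cos(2 * pi * h$order[j] * (doy - h$phase_day[j]) / 365.25)
  }
  if (!is.null(spec$school_pulse)) {
    p <- spec$school_pulse
    d <- pmin(abs(doy - p$center), 365.25 - abs(doy - p$center))
    log_seasonal <- log_seasonal + p$amp * exp(-0.5 * (d / p$width)^2)
  }
  dow <- spec$dow_multipliers[match(weekdays(dates, abbreviate = TRUE),
                                    names(spec$dow_multipliers))]
  trend <- stats::approx(as.numeric(spec$trend_knots$date),
                         spec$trend_knots$value,
                         xout = as.numeric(dates), rule = 2)$y
  mu <- spec$base_level * exp(log_seasonal) * as.numeric(dow) * trend
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop_shesd("spec implies a negative or non-finite expected count",
               "shesd_spec_error")
  }
  data.frame(date = dates, mu = mu)
}

# Calibrate base_level to an exact target mean and the NB size to a target
# SD given the deterministic mean curve (law of total variance:
# Var = mean(mu) + mean(mu^2)/size + var(mu)).  Returns the spec with
# base_level and dispersion replaced.
calibrate_spec <- function(spec, target_mean, target_sd) {
  mu <- expected_counts(spec)$mu
  spec$base_level <- spec$base_level * target_mean / mean(mu)
  mu <- mu * target_mean / mean(mu)
  excess <- target_sd^2 - stats::var(mu) - mean(mu)
  spec$dispersion <- if (excess > 0) mean(mu^2) / excess else Inf
  spec
}

#' Default synthetic admissions spec
#'
#' Calibrated so the deterministic mean curve averages 11.3 counts/day and
#' the marginal SD is 6.0 over the default 4748-day window, with seasonal
#' peaks in February (summer's end / return to school) and May (autumn's
#' end), a December-January trough, a mild day-of-week effect and a
#' long-term trend that declines to 2002 and then flattens.
#'
#' @return A [synthetic_spec()].
#' @export
default_admissions_spec <- function() {
  spec <- synthetic_spec(
    base_level = 1,
    harmonics = data.frame(amp = c(0.3184, 0.1665, 0.1229, 0.2523),
                           order = 1:4,
                           phase_day = c(129.00, 104.21, 58.10, 48.58)),
    school_pulse = list(amp = 0.45, center = 40, width = 11),
    dow_multipliers = c(Mon = 1.10, Tue = 1.04, Wed = 1.00, Thu = 0.99,
                        Fri = 0.98, Sat = 0.93, Sun = 0.96),
    trend_knots = data.frame(
      date = as.Date(c("1996-07-01", "2002-07-01", "2005-06-30",
                       "2009-06-30")),
      value = c(1.30, 0.90, 0.94, 0.88)),
    seed = 1996L, label = "synthetic-admissions"
  )
  calibrate_spec(spec, target_mean = 11.3, target_sd = 6.0)
}

#' Default synthetic readmissions spec
#'
#' A zero-dominated low-count series: mean 0.5/day, winter (June-August)
#' peak, trend declining to 2002 then rising to the end of the window.
#' More than half of the generated counts are zero, so the raw series has
#' scaled MAD 0 and exercises the jitter extension of the detector.
#'
#' @return A [synthetic_spec()].
#' @export
default_readmissions_spec <- function() {
  spec <- synthetic_spec(
    base_level = 1,
    harmonics = data.frame(amp = c(0.38, 0.10),
                           order = c(1, 2),
                           phase_day = c(200, 170)),
    dow_multipliers = c(Mon = 1.02, Tue = 1.00, Wed = 1.00, Thu = 1.00,
                        Fri = 1.00, Sat = 0.99, Sun = 0.99),
    trend_knots = data.frame(
      date = as.Date(c("1996-07-01", "2002-07-01", "2009-06-30")),
      value = c(1.20, 0.80, 1.30)),
    seed = 1996L, label = "synthetic-readmissions"
  )
  calibrate_spec(spec, target_mean = 0.5, target_sd = 0.7)
}

#' Generate a synthetic daily count series
#'
#' Draws one count per day from a negative-binomial (Poisson when
#' `dispersion = Inf`) with the spec's mean curve.  Reproducible given the
#' seed; the caller's RNG state is left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @param seed RNG seed, defaulting to `spec$seed`.
#' @return A [daily_count_series()].
#' @export
generate_series <- function(spec, seed = spec$seed) {
  mu <- expected_counts(spec)
  n <- nrow(mu)
  values <- withr::with_seed(as.integer(seed), {
    if (is.finite(spec$dispersion)) {
      stats::rnbinom(n, mu = mu$mu, size = spec$dispersion)
    } else {
      stats::rpois(n, lambda = mu$mu)
    }
  })
  daily_count_series(mu$date, values, label = spec$label)
}

#' Specification of ground-truth anomaly injection
#'
#' @param n_anomalies number of anomalous days to inject.
#' @param magnitude spike size in units of `reference_residual_scale`
#'   (typically residual scaled-MADs); with scale 1 it is an absolute
#'   count increment.
#' @param placement `"random"` (uniform over days), `"seasonal_local"`
#'   (low-season days chosen so the spiked count stays strictly below the
#'   clean series' global maximum — anomalies detectable only relative to
#'   their season), or `"dates"` (explicit `dates`).
#' @param dates explicit injection dates when `placement = "dates"`.
#' @param seed RNG seed for placement.
#' @return A list of class `injection_spec`.
#' @export
injection_spec <- function(n_anomalies, magnitude,
                           placement = c("random", "seasonal_local", "dates"),
                           dates = NULL, seed = 1L) {
  placement <- match.arg(placement)
  if (magnitude < 0) {
    stop_shesd("magnitude must be non-negative", "shesd_spec_error")
  }
  if (placement == "dates") {
    if (is.null(dates)) {
      stop_shesd("placement = 'dates' needs explicit dates", "shesd_spec_error")
    }
    dates <- as.Date(dates)
    if (anyDuplicated(dates)) {
      stop_shesd("injection dates must be unique", "shesd_spec_error")
    }
    n_anomalies <- length(dates)
  }
  structure(
    list(n_anomalies = as.integer(n_anomalies), magnitude = magnitude,
         placement = placement, dates = dates, seed = as.integer(seed)),
    class = "injection_spec"
  )
}

#' Inject ground-truth anomalies into a series
#'
#' Adds `round(magnitude * reference_residual_scale)` counts to each
#' chosen day and returns the modified series together with the truth
#' labels.  The injection is exactly additive and touches only the truth
#' dates.
#'
#' @param series a clean [daily_count_series()].
#' @param injection an [injection_spec()].
#' @param reference_residual_scale scale converting `magnitude` to counts;
#'   conventionally the scaled MAD of the clean series' STL remainder.
#' @return A list with elements `series` (spiked series), `truth` (sorted
#'   `Date` vector) and `delta` (counts added per anomalous day).
#' @export
inject_anomalies <- function(series, injection, reference_residual_scale = 1) {
  n <- length(series)
  if (injection$n_anomalies >= 0.02 * n) {
    stop_shesd("n_anomalies must stay below 2% of the series length",
               "shesd_spec_error")
  }
  delta <- round(injection$magnitude * reference_residual_scale)
  pick <- switch(injection$placement,
    random = withr::with_seed(injection$seed,
                              sort(sample.int(n, injection$n_anomalies))),
    dates = {
      j <- match(injection$dates, series$dates)
      if (anyNA(j)) {
        stop_shesd("injection dates outside the series",
                   "shesd_placement_error")
      }
      sort(j)
    },
    seasonal_local = {
      mo <- format(series$dates, "%m")
      mo_mean <- tapply(series$values, mo, mean)
      low_months <- names(mo_mean)[mo_mean < stats::median(mo_mean)]
      cand <- which(mo %in% low_months &
                      series$values + delta < max(series$values))
      if (length(cand) < injection$n_anomalies) {
        stop_shesd("not enough low-season days below the global maximum",
                   "shesd_placement_error")
      }
      withr::with_seed(injection$seed,
                       sort(sample(cand, injection$n_anomalies)))
    })
  values <- series$values
  values[pick] <- values[pick] + delta
  list(series = daily_count_series(series$dates, values,
                                   label = series$label),
       truth = series$dates[pick], delta = delta)
}
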