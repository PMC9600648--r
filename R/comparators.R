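#' Configuration of the rolling trimmed-mean comparator (TMQQ)
#'
#' Reproduces the classifier that standardizes each day against a rolling
#' 25% trimmed mean and SD (only the middle ~50% of each window is used)
#' and flags days whose standardized residual exceeds a threshold read off
#' a residual quantile-quantile plot.
#'
#' @param window odd centred window width in days.  The originating study
#'   does not state its window; 15 days is the package default and should
#'   be treated as a reproduction unknown.
#' @param trim_fraction fraction trimmed from each tail of the window.
#' @param threshold_sd `"auto"` to locate the threshold with
#'   [qq_threshold()], or a positive number of SDs (the published analyses
#'   used 10.2 for admissions and 7.5 for readmissions).
#' @param qq_gap_factor gap-factor of the automatic threshold rule.
#' @return A list of class `tmqq_config`.
#' @export
tmqq_config <- function(window = 15L, trim_fraction = 0.25,
                        threshold_sd = "auto", qq_gap_factor = 3) {
  if (trim_fraction < 0 || trim_fraction >= 0.5) {
    stop_shesd("trim_fraction must lie in [0, 0.5)", "shesd_domain_error")
  }
  if (!identical(threshold_sd, "auto") &&
      (!is.numeric(threshold_sd) || threshold_sd <= 0)) {
    stop_shesd("threshold_sd must be 'auto' or > 0", "shesd_domain_error")
  }
  structure(
    list(window = as.integer(window), trim_fraction = trim_fraction,
         threshold_sd = threshold_sd, qq_gap_factor = qq_gap_factor),
    class = c("tmqq_config", "detector_config")
  )
}

#' Automatic qq-plot departure threshold
#'
#' Automates the visual rule "find where the large residuals depart from
#' the preceding ones in a qq plot": within the upper decile of the sorted
#' residuals, locate the largest gap between consecutive order statistics;
#' if it exceeds `gap_factor` times the median gap of that decile, return
#' its midpoint.  When no such gap exists the function returns `Inf` with
#' a warning, so nothing is flagged — mirroring a qq plot with no visible
#' departure point.
#'
#' @param standardized_residuals numeric vector, length at least 50.
#' @param gap_factor multiple of the median upper-decile gap that counts
#'   as a departure (default 3).
#' @return The threshold (possibly `Inf`).
#' @export
qq_threshold <- function(standardized_residuals, gap_factor = 3) {
  x <- standardized_residuals[is.finite(standardized_residuals)]
  if (length(x) < 50) {
    stop_shesd("need at least 50 residuals to locate a qq threshold",
               "shesd_short_input_error")
  }
  s <- sort(x)
  n <- length(s)
  upper <- s[(n - ceiling(0.1 * n) + 1):n]
  gaps <- diff(upper)
  med_gap <- stats::median(gaps)
  j <- which.max(gaps)
  departs <- if (med_gap > 0) gaps[j] > gap_factor * med_gap else gaps[j] > 0
  if (!departs) {
    warn_shesd("no departure point in the residual qq plot; returning Inf",
               "shesd_no_departure_warning")
    return(Inf)
  }
  (upper[j] + upper[j + 1]) / 2
}

#' Detect high days with the rolling trimmed-mean comparator (TMQQ)
#'
#' Standardizes each count against its centred rolling trimmed mean and
#' SD, then flags days whose standardized residual exceeds the (manual or
#' qq-derived) threshold.  Only the high side is tested, matching the
#' high-admission-day use case.  Windows whose trimmed SD is zero are
#' degenerate: such days get residual 0 when they equal the trimmed mean
#' and `Inf` when they exceed it; their dates are attached to the report
#' (`extra$degenerate_dates`) and signalled as a warning.
#'
#' @param series a [daily_count_series()] at least as long as the window.
#' @param config a [tmqq_config()].
#' @return An `anomaly_report` (records: flagged days only;
#'   `significant` is `NA` — the method attaches no formal test).
#' @export
tmqq_detect <- function(series, config = tmqq_config()) {
  roll <- rolling_stat(series, config$window, config$trim_fraction)
  x <- series$values
  r <- ifelse(roll$sd > 0, (x - roll$mean) / roll$sd,
              ifelse(x > roll$mean, Inf, ifelse(x < roll$mean, -Inf, 0)))
  degenerate <- series$dates[roll$sd == 0]
  if (length(degenerate)) {
    warn_shesd(sprintf("rolling trimmed SD is zero in %d window(s)",
                       length(degenerate)),
               "shesd_degenerate_warning", dates = degenerate)
  }
  threshold <- if (identical(config$threshold_sd, "auto")) {
    qq_threshold(r, config$qq_gap_factor)
  } else config$threshold_sd

  hit <- which(r > threshold)
  hit <- hit[order(-r[hit])]
  records <- data.frame(
    date = series$dates[hit], observed = x[hit],
    residual = x[hit] - roll$mean[hit], statistic = r[hit],
    critical_value = rep(threshold, length(hit)),
    rank = seq_along(hit), flagged = rep(TRUE, length(hit)),
    significant = rep(NA, length(hit))
  )
  anomaly_report(records, method = "tmqq", date_range = range(series$dates),
                 extra = list(threshold = threshold,
                              window = config$window,
                              trim_fraction = config$trim_fraction,
                              degenerate_dates = degenerate))
}

#' Configuration of the model-based 4-SD comparator (M.4SD)
#'
#' A semiparametric generalized additive model of the daily mean count
#' with a cyclic annual seasonal smooth, a long-term trend smooth and a
#' day-of-week factor; days whose response residual (observed minus fitted
#' mean) exceeds `sd_threshold` residual SDs are flagged.
#'
#' @param sd_threshold number of residual SDs (a priori default 4).
#' @param seasonal_basis_dim basis dimension of the cyclic day-of-year
#'   smooth.
#' @param trend_basis_dim basis dimension of the long-term trend smooth.
#' @param family `"quasipoisson"` (default), `"nb"` (negative binomial)
#'   or `"gaussian_log1p"` (Gaussian fit to `log1p` counts, fitted means
#'   back-transformed).
#' @param dow_effect include the day-of-week factor (default `TRUE`).
#' @param residual_scale `"response"` (default: SD of observed minus
#'   fitted over all days, matching "4 SD from the model predicted mean")
#'   or `"pearson"`.
#' @return A list of class `m4sd_config`.
#' @export
m4sd_config <- function(sd_threshold = 4, seasonal_basis_dim = 20L,
                        trend_basis_dim = 10L,
                        family = c("quasipoisson", "nb", "gaussian_log1p"),
                        dow_effect = TRUE,
                        residual_scale = c("response", "pearson")) {
  family <- match.arg(family)
  residual_scale <- match.arg(residual_scale)
  if (sd_threshold <= 0) {
    stop_shesd("sd_threshold must be > 0", "shesd_domain_error")
  }
  structure(
    list(sd_threshold = sd_threshold,
         seasonal_basis_dim = as.integer(seasonal_basis_dim),
         trend_basis_dim = as.integer(trend_basis_dim),
         family = family, dow_effect = dow_effect,
         residual_scale = residual_scale),
    class = c("m4sd_config", "detector_config")
  )
}

#' Detect high days with the model-based 4-SD comparator (M.4SD)
#'
#' Fits the GAM described in [m4sd_config()] and flags days whose positive
#' response residual exceeds `sd_threshold` times the residual SD (the SD
#' is computed over all days after the fit, never supplied a priori).
#'
#' @param series a [daily_count_series()] spanning at least three years.
#' @param config an [m4sd_config()].
#' @return An `anomaly_report` (records: flagged days only;
#'   `significant` is `NA`).
#' @export
m4sd_detect <- function(series, config = m4sd_config()) {
  n <- length(series)
  if (n < 3 * 365) {
    stop_shesd("M.4SD needs at least three years of daily data",
               "shesd_short_series_error")
  }
  dates <- series$dates
  lt <- as.POSIXlt(dates)
  yr <- lt$year + 1900L
  year_len <- ifelse(yr %% 4 == 0 & (yr %% 100 != 0 | yr %% 400 == 0),
                     366L, 365L)
  # fractional position within the year, cyclic on [0, 1]
  doy <- (lt$yday + 0.5) / year_len
  dat <- data.frame(
    count = series$values,
    doy = doy,
    tnum = as.numeric(dates - dates[1]),
    dow = factor(weekdays(dates, abbreviate = TRUE))
  )
  rhs <- sprintf("s(doy, bs = 'cc', k = %d) + s(tnum, k = %d)%s",
                 config$seasonal_basis_dim, config$trend_basis_dim,
                 if (config$dow_effect) " + dow" else "")
  fit <- tryCatch({
    if (config$family == "gaussian_log1p") {
      mgcv::gam(stats::as.formula(paste("log1p(count) ~", rhs)),
                data = dat, knots = list(doy = c(0, 1)), method = "REML")
    } else {
      fam <- if (config$family == "nb") mgcv::nb() else stats::quasipoisson()
      mgcv::gam(stats::as.formula(paste("count ~", rhs)), family = fam,
                data = dat, knots = list(doy = c(0, 1)), method = "REML")
    }
  }, error = function(e) {
    stop_shesd(sprintf("GAM fit failed: %s", conditionMessage(e)),
               "shesd_fit_error", parent_message = conditionMessage(e))
  })
  mu <- as.numeric(stats::fitted(fit))
  if (config$family == "gaussian_log1p") mu <- pmax(expm1(mu), 0)
  resid_resp <- dat$count - mu
  scale_resid <- if (config$residual_scale == "pearson") {
    v <- if (config$family == "gaussian_log1p") rep(1, n) else pmax(mu, 1e-8)
    resid_resp / sqrt(v)
  } else resid_resp
  sd_r <- stats::sd(scale_resid)
  r <- scale_resid / sd_r

  hit <- which(r > config$sd_threshold)
  hit <- hit[order(-r[hit])]
  records <- data.frame(
    date = dates[hit], observed = series$values[hit],
    residual = resid_resp[hit], statistic = r[hit],
    critical_value = rep(config$sd_threshold, length(hit)),
    rank = seq_along(hit), flagged = rep(TRUE, length(hit)),
    significant = rep(NA, length(hit))
  )
  anomaly_report(records, method = "m4sd", date_range = range(dates),
                 extra = list(sd_threshold = config$sd_threshold,
                              family = config$family,
                              residual_sd = sd_r, fitted_mean = mu))
}

#' Run any configured detector on a series
#'
#' Dispatches on the configuration class, so heterogeneous detector lists
#' can be compared uniformly.
#'
#' @param series a [daily_count_series()].
#' @param config an [shesd_config()], [tmqq_config()] or [m4sd_config()].
#' @return An `anomaly_report`.
#' @export
run_detector <- function(series, config) {
  if (inherits(config, "shesd_config")) return(shesd_detect(series, config))
  if (inherits(config, "tmqq_config")) return(tmqq_detect(series, config))
  if (inherits(config, "m4sd_config")) return(m4sd_detect(series, config))
  stop_shesd("unknown detector configuration", "shesd_domain_error")
}
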