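#' Critical value of the generalized ESD test at removal step i
#'
#' Rosner's generalized extreme Studentized deviate test removes the most
#' extreme point at each step `i = 1..k` and compares its studentized
#' deviation against
#' \deqn{\lambda_i = \frac{(n-i)\, t_{p,\,n-i-1}}{\sqrt{(n-i-1+t^2)(n-i+1)}}}
#' with `p = 1 - alpha / (2(n-i+1))` for a two-sided test and
#' `p = 1 - alpha / (n-i+1)` one-sided.  The division of `alpha` across the
#' `n-i+1` remaining candidates is the Bonferroni-style correction built
#' into the test.
#'
#' @param n total number of observations entering the test.
#' @param i removal step (1-based); vectorised.
#' @param alpha significance level in (0, 1).
#' @param direction `"high"`, `"low"` (one-sided) or `"both"` (two-sided).
#' @return Numeric vector of critical values `lambda_i`.
#' @export
esd_critical_value <- function(n, i, alpha = 0.05,
                               direction = c("high", "low", "both")) {
  direction <- match.arg(direction)
  if (alpha <= 0 || alpha >= 1) {
    stop_shesd("alpha must lie in (0, 1)", "shesd_domain_error")
  }
  if (any(i < 1) || any(n - i - 1 < 1)) {
    stop_shesd("need n - i - 1 >= 1 at every removal step",
               "shesd_domain_error")
  }
  m <- n - i + 1          # candidates remaining before step i
  p <- if (direction == "both") 1 - alpha / (2 * m) else 1 - alpha / m
  tq <- stats::qt(p, df = n - i - 1)
  (n - i) * tq / sqrt((n - i - 1 + tq^2) * (n - i + 1))
}

#' Robust generalized ESD test with median and scaled MAD
#'
#' The hybrid core of S-H-ESD: Rosner's iterative ESD test with the sample
#' mean and SD replaced by the median and scaled MAD, both recomputed on
#' the remaining values after each removal.  At step `i` the statistic is
#' the largest deviation from the current median in units of the current
#' scaled MAD (positive deviations for `direction = "high"`, negative for
#' `"low"`, absolute for `"both"`).  The declared outlier count `k_used` is
#' the largest `i` with `C_i > lambda_i`; every candidate with rank at most
#' `k_used` is an outlier (the ESD decision rule is prefix-closed).
#'
#' @param values numeric vector, length at least `k_max + 3`.
#' @param k_max maximum number of outliers tested.
#' @param alpha significance level.
#' @param direction `"high"`, `"low"` or `"both"`.
#' @param constant MAD consistency constant.
#' @return data.frame with one row per tested candidate: `index` (position
#'   in `values`), `value`, `residual` (deviation from the median current
#'   at removal), `statistic` (`C_i`), `critical_value` (`lambda_i`),
#'   `rank` and `significant`.  Attribute `k_used` carries the declared
#'   outlier count.
#' @export
robust_esd <- function(values, k_max, alpha = 0.05,
                       direction = c("high", "low", "both"),
                       constant = 1.4826) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n < k_max + 3) {
    stop_shesd(sprintf("need length >= k_max + 3 (%d < %d)", n, k_max + 3),
               "shesd_short_input_error")
  }
  rs0 <- robust_scale(values, constant)
  if (rs0$scale == 0) {
    stop_shesd(
      "scaled MAD is zero (more than half of the values tie); jitter the series",
      "shesd_zero_mad_error")
  }

  remaining <- seq_len(n)
  idx <- integer(k_max); val <- resid <- stat <- numeric(k_max)
  lambda <- esd_critical_value(n, seq_len(k_max), alpha, direction)
  for (i in seq_len(k_max)) {
    x <- values[remaining]
    rs <- robust_scale(x, constant)
    if (rs$scale == 0) {
      stop_shesd("scaled MAD became zero during removal; jitter the series",
                 "shesd_zero_mad_error")
    }
    dev <- switch(direction,
                  high = x - rs$center,
                  low  = rs$center - x,
                  both = abs(x - rs$center))
    j <- which.max(dev)
    idx[i] <- remaining[j]
    val[i] <- x[j]
    resid[i] <- x[j] - rs$center
    stat[i] <- dev[j] / rs$scale
    remaining <- remaining[-j]
  }
  k_used <- {
    sig_steps <- which(stat > lambda)
    if (length(sig_steps)) max(sig_steps) else 0L
  }
  out <- data.frame(index = idx, value = val, residual = resid,
                    statistic = stat, critical_value = lambda,
                    rank = seq_len(k_max),
                    significant = seq_len(k_max) <= k_used)
  attr(out, "k_used") <- as.integer(k_used)
  out
}

#' Jitter an integer count series with open-interval uniform noise
#'
#' Adds an independent uniform draw strictly inside (-0.5, 0.5) to every
#' count.  This smooths a highly discrete series just enough to give it a
#' positive MAD without moving any value across an integer boundary:
#' rounding the jittered series recovers the original exactly.  The draw is
#' deterministic given `seed` and does not disturb the caller's RNG state.
#'
#' @param series an un-jittered, integer-valued [daily_count_series()].
#' @param seed integer seed for the noise draw.
#' @return The jittered series, with the `jittered` attribute set.
#' @export
jitter_series <- function(series, seed) {
  if (is_jittered(series)) {
    stop_shesd("series is already jittered", "shesd_already_jittered_error")
  }
  if (!all(is_wholenumber(series$values))) {
    stop_shesd("jitter requires an integer-valued series",
               "shesd_already_jittered_error")
  }
  n <- length(series)
  noise <- withr::with_seed(as.integer(seed), {
    u <- stats::runif(n, -0.5, 0.5)
    # runif can in principle return an endpoint; the interval must be open
    while (any(abs(u) >= 0.5)) {
      u[abs(u) >= 0.5] <- stats::runif(sum(abs(u) >= 0.5), -0.5, 0.5)
    }
    u
  })
  daily_count_series(series$dates, series$values + noise,
                     label = series$label, jittered = TRUE,
                     allow_gaps = isTRUE(attr(series, "has_gaps")))
}

#' Configuration of an S-H-ESD run
#'
#' @param alpha significance level of the ESD test (default 0.05).
#' @param k_max `"auto"` or an integer cap on the number of outliers.  The
#'   auto policy starts at `max(10, 1% of n)` and doubles whenever the test
#'   declares exactly `k` outliers (i.e. the cap may be binding), up to a
#'   hard cap of 10% of `n`, so the search is exhaustive in practice.
#' @param direction `"high"` flags only anomalously high days (the use
#'   case: high admission/readmission days); `"low"` and `"both"` are kept
#'   for parity with the originating test.
#' @param period seasonal period in days.
#' @param residual_mode `"remainder"` (default) or
#'   `"seasonal_minus_median"`; see [extract_residuals()].
#' @param seasonal_window passed to [stl_decompose()].
#' @param robust robust STL reweighting flag.
#' @param jitter `"auto"` (jitter only when the raw series has zero scaled
#'   MAD), `"on"` (always) or `"off"` (raise a zero-MAD error instead).
#' @param jitter_seed base seed for jitter draws.
#' @param jitter_replicates number of independent jitter draws; with more
#'   than one, a day is flagged when it is flagged in a strict majority of
#'   replicates, which removes the seed-dependence of borderline days.
#' @return A list of class `shesd_config`.
#' @export
shesd_config <- function(alpha = 0.05, k_max = "auto",
                         direction = c("high", "low", "both"),
                         period = 365L,
                         residual_mode = c("remainder", "seasonal_minus_median"),
                         seasonal_window = "periodic", robust = TRUE,
                         jitter = c("auto", "on", "off"),
                         jitter_seed = 20221010L, jitter_replicates = 1L) {
  direction <- match.arg(direction)
  residual_mode <- match.arg(residual_mode)
  jitter <- match.arg(jitter)
  if (alpha <= 0 || alpha >= 1) {
    stop_shesd("alpha must lie in (0, 1)", "shesd_domain_error")
  }
  if (!identical(k_max, "auto") && (!is.numeric(k_max) || k_max < 1)) {
    stop_shesd("k_max must be 'auto' or a positive integer",
               "shesd_domain_error")
  }
  if (jitter_replicates < 1) {
    stop_shesd("jitter_replicates must be >= 1", "shesd_domain_error")
  }
  structure(
    list(alpha = alpha, k_max = k_max, direction = direction,
         period = as.integer(period), residual_mode = residual_mode,
         seasonal_window = seasonal_window, robust = robust,
         jitter = jitter, jitter_seed = as.integer(jitter_seed),
         jitter_replicates = as.integer(jitter_replicates)),
    class = c("shesd_config", "detector_config")
  )
}

# One full decompose -> residual -> robust ESD pass on a (possibly
# jittered) series, with the auto-escalating k policy.
shesd_single_pass <- function(series, config) {
  dec <- stl_decompose(series, period = config$period,
                       robust = config$robust,
                       seasonal_window = config$seasonal_window)
  res <- extract_residuals(series, dec, mode = config$residual_mode)
  n <- length(res)
  k_cap <- max(10L, as.integer(floor(0.1 * n)))
  k <- if (identical(config$k_max, "auto")) {
    min(max(10L, as.integer(ceiling(0.01 * n))), k_cap)
  } else {
    min(as.integer(config$k_max), n - 3L)
  }
  repeat {
    esd <- robust_esd(res, k_max = k, alpha = config$alpha,
                      direction = config$direction)
    k_used <- attr(esd, "k_used")
    escalate <- identical(config$k_max, "auto") && k_used == k && k < k_cap
    if (!escalate) break
    k <- min(2L * k, k_cap)
  }
  list(esd = esd, residuals = res, k_used = attr(esd, "k_used"))
}

#' Detect high-count days with S-H-ESD
#'
#' The full Seasonal Hybrid ESD procedure: robust STL decomposition,
#' residual extraction, then the iterative robust ESD test with
#' Bonferroni-adjusted critical values.  If the raw series has zero scaled
#' MAD (more than half of its values tie, typical of low-count readmission
#' series), `jitter = "auto"` adds open-interval uniform(-0.5, 0.5) noise
#' before decomposition and re-runs; with `jitter = "off"` the condition is
#' raised as an error instead.  With `jitter_replicates > 1` the detection
#' is repeated under independent jitter draws and a day is flagged when a
#' strict majority of replicates flag it.
#'
#' Flagged days are always reported with their original (integer) counts,
#' even when detection ran on jittered values.
#'
#' @param series a gap-free [daily_count_series()] of length at least
#'   `2 * period`.
#' @param config an [shesd_config()].
#' @return An `anomaly_report`; records hold every tested candidate of the
#'   (first) ESD pass in removal order, with `flagged`/`significant` set by
#'   the decision rule (majority vote across replicates when applicable).
#'   `extra$adjusted_alpha` reports `alpha / k_used`, the per-outlier
#'   Bonferroni share of the significance level.
#' @export
shesd_detect <- function(series, config = shesd_config()) {
  if (length(series) <= 2 * config$period) {
    stop_shesd("series must exceed two seasonal periods",
               "shesd_short_series_error")
  }
  raw <- series
  needs_jitter <- !is_jittered(series) &&
    robust_scale(series$values)$scale == 0
  use_jitter <- switch(config$jitter,
    off = if (needs_jitter) {
      stop_shesd(
        "scaled MAD of the series is zero (more than half of the counts tie); set jitter = 'auto' or 'on'",
        "shesd_zero_mad_error")
    } else FALSE,
    on = !is_jittered(series),
    auto = needs_jitter)

  n_rep <- if (use_jitter) config$jitter_replicates else 1L
  passes <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    s_r <- if (use_jitter) {
      jitter_series(raw, seed = config$jitter_seed + r - 1L)
    } else series
    passes[[r]] <- tryCatch(
      shesd_single_pass(s_r, config),
      shesd_zero_mad_error = function(e) {
        # residual MAD degenerated mid-test despite an integer series that
        # passed the raw-series check: fall back to a jittered re-run
        if (config$jitter == "off" || use_jitter) stop(e)
        shesd_single_pass(jitter_series(raw, seed = config$jitter_seed + r - 1L),
                          config)
      })
  }

  first <- passes[[1L]]
  esd <- first$esd
  if (n_rep > 1L) {
    votes <- table(do.call(c, lapply(passes, function(p) {
      as.character(raw$dates[p$esd$index[p$esd$significant]])
    })))
    majority <- as.Date(names(votes)[votes > n_rep / 2])
    esd$significant <- raw$dates[esd$index] %in% majority
  }
  k_used <- sum(esd$significant)

  records <- data.frame(
    date = raw$dates[esd$index],
    observed = raw$values[esd$index],   # original integer counts
    residual = first$residuals[esd$index],
    statistic = esd$statistic,
    critical_value = esd$critical_value,
    rank = esd$rank,
    flagged = esd$significant,
    significant = esd$significant
  )
  anomaly_report(
    records, method = "shesd", alpha = config$alpha,
    k_used = as.integer(k_used), jitter_applied = use_jitter,
    date_range = range(raw$dates),
    extra = list(adjusted_alpha = if (k_used > 0) config$alpha / k_used
                                  else NA_real_,
                 direction = config$direction,
                 residual_mode = config$residual_mode,
                 n_replicates = n_rep)
  )
}
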