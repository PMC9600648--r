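#' Score a detector against ground-truth anomaly dates
#'
#' Matches flagged days to truth days one-to-one, greedily by date
#' distance (exact-day matching by default).  Sensitivity is
#' `TP / (TP + FN)`; positive predictive value is `TP / (TP + FP)`, left
#' undefined (`NA`) when nothing was detected.
#'
#' @param report an `anomaly_report`.
#' @param truth `Date` vector of true anomalous days, inside the report's
#'   series range.
#' @param tolerance_days maximal |detected - truth| gap counting as a
#'   match (default 0, exact day).
#' @return A list of class `detection_metrics`: `sensitivity`, `ppv`,
#'   `true_positives`, `false_positives`, `false_negatives`, `n_truth`,
#'   `n_detected`.
#' @export
score_detections <- function(report, truth, tolerance_days = 0L) {
  truth <- as.Date(truth)
  if (!is.null(report$date_range) && length(truth) &&
      (min(truth) < report$date_range[1] || max(truth) > report$date_range[2])) {
    stop_shesd("truth dates fall outside the report's series range",
               "shesd_range_mismatch_error")
  }
  detected <- flagged_dates(report)
  # greedy one-to-one matching by increasing date distance
  pairs <- expand.grid(d = seq_along(detected), t = seq_along(truth))
  if (nrow(pairs)) {
    pairs$dist <- abs(as.numeric(detected[pairs$d] - truth[pairs$t]))
    pairs <- pairs[pairs$dist <= tolerance_days, , drop = FALSE]
    pairs <- pairs[order(pairs$dist), , drop = FALSE]
  }
  used_d <- logical(length(detected)); used_t <- logical(length(truth))
  tp <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$d[r]; j <- pairs$t[r]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- used_t[j] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(truth) - tp
  structure(
    list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         true_positives = tp, false_positives = fp, false_negatives = fn,
         n_truth = length(truth), n_detected = length(detected)),
    class = "detection_metrics"
  )
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf(
    "<detection_metrics: sensitivity %s, PPV %s (TP %d, FP %d, FN %d)>\n",
    format(x$sensitivity, digits = 3),
    if (is.na(x$ppv)) "undefined" else format(x$ppv, digits = 3),
    x$true_positives, x$false_positives, x$false_negatives))
  invisible(x)
}

# month ordering used in the seasonality tables: December (austral summer
# start) through November, so each southern-hemisphere season is contiguous
south_month_levels <- function() month.name[c(12, 1:11)]

#' Flagged days by month of occurrence
#'
#' Seasonality summary: counts and exact column percentages of flagged
#' days per calendar month, December first (southern-hemisphere season
#' order).
#'
#' @param report an `anomaly_report`.
#' @return `data.frame(month, count, pct)` with 12 rows; attribute
#'   `total` holds the number of flagged days.
#' @export
month_table <- function(report) {
  d <- flagged_dates(report)
  m <- factor(months(d), levels = south_month_levels())
  counts <- as.integer(table(m))
  total <- length(d)
  out <- data.frame(month = south_month_levels(), count = counts,
                    pct = if (total > 0) 100 * counts / total else rep(0, 12))
  attr(out, "total") <- total
  out
}

#' Flagged days before and after a split date
#'
#' Time-trend summary mirroring the pre/post-2002 comparison: counts and
#' percentages of flagged days on or before versus after the split.
#'
#' @param report an `anomaly_report`.
#' @param split split date (default 2002-12-31).
#' @return Two-row `data.frame(period, count, pct)`.
#' @export
period_split_table <- function(report, split = as.Date("2002-12-31")) {
  d <- flagged_dates(report)
  split <- as.Date(split)
  pre <- sum(d <= split); post <- sum(d > split); total <- length(d)
  data.frame(
    period = c(sprintf("<= %s", format(split, "%Y")),
               sprintf("> %s", format(split, "%Y"))),
    count = c(pre, post),
    pct = if (total > 0) 100 * c(pre, post) / total else c(0, 0))
}

#' Run several detectors on one series and summarize their overlap
#'
#' @param series a [daily_count_series()].
#' @param configs named list of detector configurations (see
#'   [run_detector()]); at least two.
#' @return A list of class `method_comparison`: `flags` (one row per day
#'   flagged by any method, with per-method indicator columns and
#'   `n_methods`), `overlap` (how many days were flagged by exactly 1, 2,
#'   ... methods) and `reports` (the individual reports).
#' @export
compare_methods <- function(series, configs) {
  if (length(configs) < 2) {
    stop_shesd("need at least two detector configurations",
               "shesd_domain_error")
  }
  if (is.null(names(configs)) || any(names(configs) == "")) {
    names(configs) <- paste0("method", seq_along(configs))
  }
  reports <- lapply(names(configs), function(nm) {
    tryCatch(run_detector(series, configs[[nm]]), error = function(e) {
      stop_shesd(sprintf("detector '%s' failed: %s", nm,
                         conditionMessage(e)),
                 "shesd_fit_error", method = nm)
    })
  })
  names(reports) <- names(configs)
  flag_sets <- lapply(reports, flagged_dates)
  all_days <- sort(unique(do.call(c, flag_sets)))
  ind <- vapply(flag_sets, function(f) all_days %in% f,
                logical(length(all_days)))
  ind <- matrix(ind, nrow = length(all_days),
                dimnames = list(NULL, names(configs)))
  flags <- data.frame(date = all_days,
                      observed = series$values[match(all_days, series$dates)])
  flags <- cbind(flags, as.data.frame(ind))
  flags$n_methods <- rowSums(ind)
  overlap <- as.data.frame(table(factor(flags$n_methods,
                                        levels = seq_along(configs))))
  names(overlap) <- c("n_methods", "n_days")
  overlap$n_methods <- as.integer(as.character(overlap$n_methods))
  structure(list(flags = flags, overlap = overlap, reports = reports),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison: %d method(s), %d distinct flagged day(s)>\n",
              length(x$reports), nrow(x$flags)))
  print(x$overlap)
  invisible(x)
}

#' Monte-Carlo validation of a detector with injected ground truth
#'
#' For each replicate: generate a fresh synthetic series, measure its
#' residual scale (scaled MAD of the robust STL remainder of the clean
#' series), inject anomalies at the requested magnitude, detect, and
#' score.  Reports per-replicate metrics plus means and Monte-Carlo
#' standard errors; PPV is averaged over replicates with at least one
#' detection (the count of skipped replicates is reported).
#'
#' @param n_replicates number of Monte-Carlo replicates.
#' @param injection an [injection_spec()]; its seed is re-derived per
#'   replicate from `master_seed`.
#' @param config detector configuration (default [shesd_config()]).
#' @param master_seed master RNG seed; the whole experiment is
#'   reproducible given it.
#' @param spec synthetic series spec (default
#'   [default_admissions_spec()]).
#' @return A list of class `validation_result`: `summary` (one-row
#'   data.frame with mean sensitivity/PPV, their MC standard errors,
#'   totals, and `n_no_detection`) and `replicates` (per-replicate
#'   data.frame).
#' @export
run_validation_experiment <- function(n_replicates, injection,
                                      config = shesd_config(),
                                      master_seed = 2022L,
                                      spec = default_admissions_spec()) {
  if (n_replicates < 1) {
    stop_shesd("n_replicates must be >= 1", "shesd_domain_error")
  }
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    seed_r <- (as.integer(master_seed) + 7919L * r) %% .Machine$integer.max
    clean <- generate_series(spec, seed = seed_r)
    dec <- stl_decompose(clean, period = config$period %||% 365L)
    ref_scale <- robust_scale(dec$remainder)$scale
    inj_r <- injection
    inj_r$seed <- seed_r + 1L
    spiked <- inject_anomalies(clean, inj_r, ref_scale)
    report <- run_detector(spiked$series, config)
    m <- score_detections(report, spiked$truth)
    rows[[r]] <- data.frame(
      replicate = r, seed = seed_r, sensitivity = m$sensitivity,
      ppv = m$ppv, true_positives = m$true_positives,
      false_positives = m$false_positives,
      false_negatives = m$false_negatives, n_detected = m$n_detected,
      delta = spiked$delta)
  }
  reps <- do.call(rbind, rows)
  ppv_ok <- !is.na(reps$ppv)
  mc_se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  summary <- data.frame(
    n_replicates = n_replicates,
    mean_sensitivity = mean(reps$sensitivity),
    se_sensitivity = mc_se(reps$sensitivity),
    mean_ppv = if (any(ppv_ok)) mean(reps$ppv[ppv_ok]) else NA_real_,
    se_ppv = if (any(ppv_ok)) mc_se(reps$ppv[ppv_ok]) else NA_real_,
    n_no_detection = sum(!ppv_ok),
    total_tp = sum(reps$true_positives),
    total_fp = sum(reps$false_positives),
    total_fn = sum(reps$false_negatives))
  structure(list(summary = summary, replicates = reps),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<validation_result: %d replicate(s)>\n  sensitivity %.4f (MC se %.4f)\n  PPV         %s (MC se %s; %d replicate(s) without detections)\n  TP %d / FP %d / FN %d\n",
    s$n_replicates, s$mean_sensitivity, s$se_sensitivity,
    ifelse(is.na(s$mean_ppv), "undefined", sprintf("%.4f", s$mean_ppv)),
    ifelse(is.na(s$se_ppv), "-", sprintf("%.4f", s$se_ppv)),
    s$n_no_detection, s$total_tp, s$total_fp, s$total_fn))
  invisible(x)
}

#' Plot a daily count series with flagged days
#'
#' Basic series-with-flags view: the count series as a line with flagged
#' days overplotted as filled points.
#'
#' @param series a [daily_count_series()].
#' @param report optional `anomaly_report` on the same series.
#' @param ... further arguments to [plot()].
#' @return `NULL`, invisibly.
#' @export
plot_flags <- function(series, report = NULL, ...) {
  graphics::plot(series$dates, series$values, type = "l", col = "grey40",
                 xlab = "date", ylab = "daily count",
                 main = series$label, ...)
  if (!is.null(report)) {
    f <- flagged_dates(report)
    j <- match(f, series$dates)
    graphics::points(series$dates[j], series$values[j], pch = 19,
                     col = "firebrick")
  }
  invisible(NULL)
}
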