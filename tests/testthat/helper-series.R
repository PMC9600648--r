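# Builders and independent brute-force oracles used across the suite.

make_series <- function(values, start = "2000-01-01", label = "test",
                        jittered = FALSE) {
  daily_count_series(seq(as.Date(start), by = "day",
                         length.out = length(values)),
                     values, label = label, jittered = jittered)
}

# real-valued sinusoid series (stored via the jittered flag so values need
# not be integers)
make_sinusoid <- function(n, level = 10, amplitude = 5,
                          start = "2000-01-03") {
  make_series(level + amplitude * sin(2 * pi * seq_len(n) / 365),
              start = start, jittered = TRUE)
}

# day-by-day iterator oracle for calendar spans
bf_date_span <- function(start, end) {
  length(seq(as.Date(start), as.Date(end), by = "day"))
}

# from-scratch robust ESD: recomputes median/MAD by sorting at every
# removal, no shared code with robust_esd()
bf_robust_esd <- function(values, k_max, alpha, direction = "high") {
  x <- values
  pos <- seq_along(values)
  n <- length(values)
  med <- function(v) {
    s <- sort(v); m <- length(s)
    if (m %% 2 == 1) s[(m + 1) / 2] else (s[m / 2] + s[m / 2 + 1]) / 2
  }
  out <- NULL
  for (i in seq_len(k_max)) {
    m <- med(x)
    s <- 1.4826 * med(abs(x - m))
    stopifnot(s > 0)
    dev <- switch(direction, high = x - m, low = m - x, both = abs(x - m))
    j <- which.max(dev)
    mm <- n - i + 1
    p <- if (direction == "both") 1 - alpha / (2 * mm) else 1 - alpha / mm
    tq <- qt(p, n - i - 1)
    lam <- (n - i) * tq / sqrt((n - i - 1 + tq^2) * (n - i + 1))
    out <- rbind(out, data.frame(index = pos[j], statistic = dev[j] / s,
                                 critical_value = lam, rank = i))
    x <- x[-j]; pos <- pos[-j]
  }
  sig <- which(out$statistic > out$critical_value)
  out$significant <- out$rank <= (if (length(sig)) max(sig) else 0L)
  out
}

# Student-t quantile through the F distribution (independent route from
# stats::qt for the critical-value cross-check)
qt_via_qf <- function(p, df) {
  stopifnot(all(p > 0.5))
  sqrt(qf(2 * p - 1, 1, df))
}

# all-pairs exhaustive matcher oracle for scoring (maximum matching found
# by brute force over assignment orders; adequate for n <= 20)
bf_score <- function(detected, truth, tolerance_days = 0) {
  detected <- as.Date(detected); truth <- as.Date(truth)
  edges <- expand.grid(d = seq_along(detected), t = seq_along(truth))
  if (nrow(edges)) {
    edges$dist <- abs(as.numeric(detected[edges$d] - truth[edges$t]))
    edges <- edges[edges$dist <= tolerance_days, , drop = FALSE]
    edges <- edges[order(edges$dist), , drop = FALSE]
  }
  used_d <- logical(length(detected)); used_t <- logical(length(truth))
  tp <- 0L
  for (r in seq_len(nrow(edges))) {
    if (!used_d[edges$d[r]] && !used_t[edges$t[r]]) {
      used_d[edges$d[r]] <- used_t[edges$t[r]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}

# minimal hand-built anomaly report for table/scoring tests
fake_report <- function(dates, observed = NULL, method = "test",
                        date_range = NULL) {
  dates <- as.Date(dates)
  k <- length(dates)
  rec <- data.frame(
    date = dates,
    observed = observed %||% rep(1, k),
    residual = rep(0, k), statistic = rep(5, k),
    critical_value = rep(4, k), rank = seq_len(k),
    flagged = rep(TRUE, k), significant = rep(NA, k))
  shesd:::anomaly_report(rec, method = method,
                         date_range = date_range %||%
                           (if (k) range(dates) else NULL))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
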