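test_that("read_series parses, orders and validates two-column files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,count", "2000-01-02,0", "2000-01-01,4", "2000-01-03,7"),
             path)
  s <- read_series(path)
  expect_s3_class(s, "daily_count_series")
  expect_length(s, 3)
  expect_equal(s$values, c(4, 0, 7))  # reordered by date
  expect_equal(s$dates, as.Date(c("2000-01-01", "2000-01-02", "2000-01-03")))

  writeLines(c("date,count", "2000-01-01,4", "2000-01-01,5"), path)
  expect_error(read_series(path), class = "shesd_parse_error")
  writeLines(c("date,count", "2000-01-01,4", "2000-01-03,5"), path)
  expect_error(read_series(path), class = "shesd_gap_error")
  expect_no_error(read_series(path, allow_gaps = TRUE))
  writeLines(c("date,count", "2000-01-01,4", "2000-01-02,-1"), path)
  expect_error(read_series(path), class = "shesd_negative_count_error")
  writeLines(c("date,count", "2000-01-01,4", "not-a-date,5"), path)
  expect_error(read_series(path), class = "shesd_parse_error")
})

test_that("write_series / read_series round-trips valid series", {
  s <- make_series(c(4, 0, 7, 2, 13), start = "1996-07-01", label = "rt")
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(s, path)
  s2 <- read_series(path, label = "rt")
  expect_equal(s2$dates, s$dates)
  expect_equal(s2$values, s$values)
})

test_that("date_span_days is inclusive, leap-aware and matches iteration", {
  expect_identical(date_span_days("1996-07-01", "2009-06-30"), 4748L)
  expect_identical(date_span_days("2000-01-01", "2000-01-01"), 1L)
  expect_identical(date_span_days("2000-02-28", "2000-03-01"), 3L)  # leap day
  expect_identical(date_span_days("2001-02-28", "2001-03-01"), 2L)
  expect_error(date_span_days("2001-01-02", "2001-01-01"),
               class = "shesd_order_error")

  withr::with_seed(42, {
    origins <- as.Date("1900-01-01") + sample.int(73000, 200)
    spans <- sample.int(3000, 200)
    for (i in seq_len(200)) {
      expect_identical(date_span_days(origins[i], origins[i] + spans[i]),
                       bf_date_span(origins[i], origins[i] + spans[i]))
    }
  })
})

test_that("robust_scale computes median and scaled MAD with breakdown at ties", {
  rs <- robust_scale(c(5, 5, 5, 5, 5))
  expect_equal(rs$center, 5)
  expect_equal(rs$scale, 0)
  rs <- robust_scale(1:5)
  expect_equal(rs$center, 3)
  expect_equal(rs$scale, 1.4826)
  # more than half the values tie -> zero scale, the jitter trigger
  expect_equal(robust_scale(c(0, 0, 0, 0, 0, 0, 1, 2, 1, 3))$scale, 0)
  expect_error(robust_scale(numeric(0)), class = "shesd_empty_input_error")
})

test_that("robust_scale is shift-invariant and positively scale-equivariant", {
  withr::with_seed(7, {
    for (i in 1:20) {
      x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 5))
      a <- runif(1, -10, 10); b <- runif(1, 0.1, 8)
      r0 <- robust_scale(x); r1 <- robust_scale(a + b * x)
      expect_equal(r1$center, a + b * r0$center)
      expect_equal(r1$scale, b * r0$scale)
    }
  })
})

test_that("trimmed_mean_sd drops floor(trim * n) from each tail", {
  r <- trimmed_mean_sd(1:10, 0.25)          # floor(2.5) = 2 per side
  expect_equal(unname(r["mean"]), mean(3:8))
  expect_equal(unname(r["sd"]), sd(3:8))
  r <- trimmed_mean_sd(c(7, 7, 7), 0.25)
  expect_equal(unname(r), c(7, 0))
  r <- trimmed_mean_sd(c(1, 2, 3, 4, 100), 0.2)  # one per side
  expect_equal(unname(r["mean"]), 3)
  # trim 0 is the plain mean/sd; base R's trimmed mean is the oracle
  withr::with_seed(11, {
    x <- rgamma(23, 2)
    expect_equal(unname(trimmed_mean_sd(x, 0)["mean"]), mean(x))
    expect_equal(unname(trimmed_mean_sd(x, 0)["sd"]), sd(x))
    expect_equal(unname(trimmed_mean_sd(x, 0.25)["mean"]),
                 mean(x, trim = 0.25))
    # the trimmed mean ignores how large the largest value is
    y <- x; y[which.max(y)] <- max(y) + 1e6
    expect_equal(unname(trimmed_mean_sd(y, 0.25)["mean"]),
                 unname(trimmed_mean_sd(x, 0.25)["mean"]))
  })
  expect_error(trimmed_mean_sd(c(1, 2, 3), 0.4),
               class = "shesd_degenerate_error")
  expect_error(trimmed_mean_sd(1:10, 0.5), class = "shesd_domain_error")
})

test_that("rolling_stat uses centred windows that shrink at the edges", {
  s <- make_series(rep(4, 30))
  r <- rolling_stat(s, 5)
  expect_equal(r$mean, rep(4, 30))
  expect_equal(r$sd, rep(0, 30))

  s <- make_series(c(0, 3, 1, 4, 1, 5, 9, 2, 6, 5, 3))
  r <- rolling_stat(s, 11, trim_fraction = 0)
  expect_equal(r$mean[6], mean(s$values))  # full-length window at centre
  expect_equal(r$sd[6], sd(s$values))

  # brute-force recomputation, including the shrinking-window edge rule
  s <- make_series(c(rep(0, 5), rep(10, 5)))
  r <- rolling_stat(s, 5, trim_fraction = 0.25)
  n <- length(s)
  for (t in seq_len(n)) {
    w <- s$values[max(1, t - 2):min(n, t + 2)]
    expect_gte(length(w), 3)  # never fewer than ceiling(window/2) points
    k <- floor(0.25 * length(w))
    kept <- sort(w)[(k + 1):(length(w) - k)]
    expect_equal(r$mean[t], mean(kept))
  }

  expect_error(rolling_stat(s, 4), class = "shesd_window_error")
  expect_error(rolling_stat(s, 11), class = "shesd_window_error")
})

test_that("daily_count_series enforces its invariants", {
  expect_error(make_series(c(1, -2, 3)), class = "shesd_negative_count_error")
  expect_error(make_series(c(1, 2.5, 3)), class = "shesd_parse_error")
  expect_no_error(make_series(c(1, 2.5, 3), jittered = TRUE))
  d <- as.Date(c("2000-01-01", "2000-01-03"))
  expect_error(daily_count_series(d, c(1, 2)), class = "shesd_gap_error")
  s <- daily_count_series(d, c(1, 2), allow_gaps = TRUE)
  expect_true(attr(s, "has_gaps"))
})
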