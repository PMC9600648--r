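test_that("ESD critical values match Rosner's worked example and an independent route", {
  # classical two-sided worked example: n = 54, first removal, alpha 0.05
  expect_equal(esd_critical_value(54, 1, 0.05, "both"), 3.1588,
               tolerance = 1e-4)

  # cross-check against lambda computed with t-quantiles derived via the
  # F distribution, over a grid
  for (n in c(30, 54, 100, 500)) {
    for (alpha in c(0.01, 0.05, 0.10)) {
      for (dir in c("high", "both")) {
        i <- 1:5
        m <- n - i + 1
        p <- if (dir == "both") 1 - alpha / (2 * m) else 1 - alpha / m
        tq <- qt_via_qf(p, n - i - 1)
        ref <- (n - i) * tq / sqrt((n - i - 1 + tq^2) * (n - i + 1))
        expect_equal(esd_critical_value(n, i, alpha, dir), ref,
                     tolerance = 1e-6)
      }
    }
  }

  # monotonicity: decreasing in removal rank, increasing in strictness
  lam <- esd_critical_value(100, 1:10, 0.05, "both")
  expect_true(all(diff(lam) < 0))
  expect_gt(esd_critical_value(100, 1, 0.01, "both"),
            esd_critical_value(100, 1, 0.10, "both"))

  expect_error(esd_critical_value(5, 4, 0.05), class = "shesd_domain_error")
  expect_error(esd_critical_value(54, 1, 1.2), class = "shesd_domain_error")
})

test_that("robust_esd agrees with a from-scratch oracle on random vectors", {
  withr::with_seed(101, {
    for (rep in 1:100) {
      n <- sample(20:60, 1)
      x <- rnorm(n)
      if (rep %% 3 == 0) x[sample(n, 2)] <- x[sample(n, 2)] + 8
      dir <- sample(c("high", "low", "both"), 1)
      k <- sample(3:6, 1)
      got <- robust_esd(x, k_max = k, alpha = 0.05, direction = dir)
      ref <- bf_robust_esd(x, k_max = k, alpha = 0.05, direction = dir)
      expect_equal(got$index, ref$index)
      expect_equal(got$statistic, ref$statistic, tolerance = 1e-12)
      expect_equal(got$critical_value, ref$critical_value, tolerance = 1e-12)
      expect_identical(got$significant, ref$significant)
    }
  })
})

test_that("robust_esd flags a planted gross outlier and nothing on a ramp", {
  x <- withr::with_seed(5, rnorm(50))
  out <- robust_esd(c(x, 100), k_max = 3, alpha = 0.05, direction = "both")
  expect_identical(which(out$significant), 1L)
  expect_identical(out$index[1], 51L)
  expect_identical(attr(out, "k_used"), 1L)

  ramp <- robust_esd(as.numeric(1:20), k_max = 3, alpha = 0.05,
                     direction = "both")
  expect_identical(attr(ramp, "k_used"), 0L)
  expect_false(any(ramp$significant))
})

test_that("robust_esd is prefix-closed and raises on zero MAD", {
  x <- withr::with_seed(9, c(rnorm(40), 6, 7, 9))
  out <- robust_esd(x, k_max = 6, alpha = 0.05, direction = "high")
  k <- attr(out, "k_used")
  expect_identical(out$significant, out$rank <= k)

  expect_error(robust_esd(c(5, 5, 5, 5, 5, 5, 5, 1, 2), k_max = 2),
               class = "shesd_zero_mad_error")
})

test_that("jitter is open-interval, invertible by rounding, and seeded", {
  s <- generate_series(default_readmissions_spec(), seed = 8)
  j1 <- jitter_series(s, seed = 1)
  expect_true(all(abs(j1$values - s$values) < 0.5))
  expect_identical(round(j1$values), s$values)
  expect_true(attr(j1, "jittered"))
  # the zero-MAD breakdown is repaired
  expect_equal(robust_scale(s$values)$scale, 0)
  expect_gt(robust_scale(j1$values)$scale, 0)
  # determinism
  expect_identical(jitter_series(s, seed = 1)$values, j1$values)
  expect_false(identical(jitter_series(s, seed = 2)$values, j1$values))
  expect_error(jitter_series(j1, seed = 1),
               class = "shesd_already_jittered_error")
})

test_that("shesd_detect finds large injected spikes with their original counts", {
  clean <- generate_series(default_admissions_spec(), seed = 404)
  scale <- robust_scale(stl_decompose(clean)$remainder)$scale
  spiked <- inject_anomalies(clean,
                             injection_spec(12, 8, "random", seed = 405),
                             scale)
  report <- shesd_detect(spiked$series)
  expect_s3_class(report, "anomaly_report")
  expect_true(all(spiked$truth %in% flagged_dates(report)))
  # flagged records report the (integer) series counts
  f <- report$records[report$records$flagged, ]
  expect_identical(f$observed,
                   spiked$series$values[match(f$date, spiked$series$dates)])
  # ESD decision rule: statistic exceeds critical value on flagged ranks
  expect_true(all(f$statistic > f$critical_value))
})

test_that("detection is equivariant under count shifts and positive scaling", {
  s <- generate_series(default_admissions_spec(), seed = 550)
  scale <- robust_scale(stl_decompose(s)$remainder)$scale
  spiked <- inject_anomalies(s, injection_spec(5, 8, "random", seed = 551),
                             scale)$series
  base_flags <- flagged_dates(shesd_detect(spiked))
  shifted <- daily_count_series(spiked$dates, spiked$values + 7)
  expect_identical(flagged_dates(shesd_detect(shifted)), base_flags)
  scaled <- daily_count_series(spiked$dates, spiked$values * 3)
  expect_identical(flagged_dates(shesd_detect(scaled)), base_flags)
})

test_that("a seasonally-local anomaly below the global maximum is flagged", {
  clean <- generate_series(default_admissions_spec(), seed = 606)
  dec <- stl_decompose(clean)
  scale <- robust_scale(dec$remainder)$scale
  spiked <- inject_anomalies(clean,
                             injection_spec(3, 6, "seasonal_local",
                                            seed = 607), scale)
  expect_true(all(
    spiked$series$values[match(spiked$truth, spiked$series$dates)] <
      max(clean$values)))
  report <- shesd_detect(spiked$series)
  expect_true(all(spiked$truth %in% flagged_dates(report)))
})

test_that("zero-MAD series error out with jitter off and complete with auto", {
  s <- generate_series(default_readmissions_spec(), seed = 700)
  expect_error(shesd_detect(s, shesd_config(jitter = "off")),
               class = "shesd_zero_mad_error")
  report <- shesd_detect(s, shesd_config(jitter = "auto"))
  expect_true(report$jitter_applied)
  expect_gt(length(flagged_dates(report)), 0)
})

test_that("majority vote over jitter replicates reduces seed dependence", {
  s <- generate_series(default_readmissions_spec(), seed = 711)
  seeds <- c(11L, 210L, 3003L, 40004L)
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  pairwise <- function(sets) {
    p <- combn(length(sets), 2)
    mean(vapply(seq_len(ncol(p)),
                function(j) jaccard(sets[[p[1, j]]], sets[[p[2, j]]]),
                numeric(1)))
  }
  single <- lapply(seeds, function(seed) {
    flagged_dates(shesd_detect(s, shesd_config(jitter_seed = seed)))
  })
  voted <- lapply(seeds, function(seed) {
    flagged_dates(shesd_detect(
      s, shesd_config(jitter_replicates = 25L, jitter_seed = seed)))
  })
  # voting across 25 draws makes the flagged set more stable than a single
  # draw; borderline days (counts of 3) may still flip with the seed
  expect_gt(pairwise(voted), pairwise(single))
  high <- s$dates[s$values >= 4]
  for (v in voted) {
    # the unambiguous high days (counts >= 4) are flagged under every seed
    expect_true(all(high %in% v))
    # and no low-count day is ever carried in by a jitter draw
    expect_true(all(s$values[match(v, s$dates)] >= 3))
  }
})

test_that("config validation rejects out-of-range settings", {
  expect_error(shesd_config(alpha = 0), class = "shesd_domain_error")
  expect_error(shesd_config(k_max = 0), class = "shesd_domain_error")
  expect_error(shesd_config(jitter_replicates = 0),
               class = "shesd_domain_error")
  expect_error(shesd_detect(make_series(rep(3, 100))),
               class = "shesd_short_series_error")
})
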