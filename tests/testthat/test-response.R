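test_that("moving-average smoothing matches a literal windowed mean", {
  # constant series is unchanged
  a <- mk_minute_ts(rep(0.2, 200))
  expect_equal(smooth_series(a)$activity, rep(0.2, 200))

  # unit impulse spreads into a 1/30 plateau over the covering windows
  imp <- numeric(200); imp[100] <- 1
  sm <- smooth_series(mk_minute_ts(imp))$activity
  expect_equal(max(sm), 1 / 30)
  expect_equal(sum(sm > 0), 30L)

  # random series with NAs: literal truncated-window oracle
  set.seed(11)
  x <- runif(300)
  x[sample(300, 25)] <- NA
  got <- smooth_series(mk_minute_ts(x))$activity
  ref <- vapply(seq_along(x), function(i) {
    w <- x[max(1, i - 15):min(length(x), i + 14)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  expect_equal(got, ref)

  expect_error(smooth_series(mk_minute_ts(0.1)), "at least 2")
})

test_that("rectangular pulse gives the closed-form FWHM after smoothing", {
  # 60-min pulse, height 1, baseline 0: trapezoid with 30-min ramps,
  # plateau 1, half-max width 60
  v <- numeric(360)
  v[61:120] <- 1
  sm <- smooth_series(mk_minute_ts(v))
  expect_equal(max(sm$activity), 1)
  r <- find_response(sm, T0 + 60 * 60, search_window = c(-180, 180))
  expect_equal(r$peak_value, 1)
  expect_lte(abs(r$fwhm_duration - 60), 1)
  expect_equal(r$average_in_fwhm <= r$peak_value, TRUE)
})

test_that("block merging follows the 5-minute rule", {
  base <- function(gap) {
    v <- numeric(240)
    v[101:110] <- 0.8            # block 1
    v[(111 + gap):(125 + gap)] <- 1.0   # block 2, holds the max
    mk_minute_ts(v)
  }
  # find_response on an already-flat series: use window as-is without
  # additional smoothing by smoothing with window 1
  resp <- function(gap) {
    s <- base(gap)
    attr(s, "smoothed") <- 1
    find_response(s, T0 + 100 * 60, search_window = c(-60, 120))
  }
  r4 <- resp(4)   # 4-min gap: merged into one block
  expect_equal(r4$fwhm_duration, 10 + 4 + 15)
  r6 <- resp(6)   # 6-min gap: second block only
  expect_equal(r6$fwhm_duration, 15)
  r5 <- resp(5)   # exactly 5 min: not merged ("less than 5 minutes")
  expect_equal(r5$fwhm_duration, 15)
})

test_that("find_response equals the brute-force block oracle on random series", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(120:600, 1)
    v <- pmax(0, stats::filter(rnorm(n, 0.1, 0.08), rep(1 / 5, 5),
                               circular = TRUE))
    v <- as.numeric(v)
    s <- mk_minute_ts(v)
    attr(s, "smoothed") <- 1
    r <- find_response(s, T0, search_window = c(0, n))
    ref <- naive_fwhm(v)
    expect_equal(r$fwhm_duration, ref$duration)
    expect_equal(r$peak_value, ref$peak)
    expect_equal(r$time_to_peak, which.max(v) - 1)
  }
})

test_that("response metrics are shift-equivariant and scale-invariant", {
  set.seed(31)
  v <- pmax(0, 0.05 + 0.2 * exp(-(seq_len(400) - 180)^2 / 900) +
                 rnorm(400, 0, 0.01))
  s <- smooth_series(mk_minute_ts(v))
  r <- find_response(s, T0 + 120 * 60, search_window = c(-60, 240))

  # time shift by 37 min shifts the interval, not the durations
  s2 <- smooth_series(mk_minute_ts(v, start = T0 + 37 * 60))
  r2 <- find_response(s2, T0 + 157 * 60, search_window = c(-60, 240))
  expect_equal(r2$fwhm_duration, r$fwhm_duration)
  expect_equal(r2$time_to_peak, r$time_to_peak)
  expect_equal(as.numeric(r2$fwhm_start) - as.numeric(r$fwhm_start), 37 * 60)

  # positive scaling leaves times unchanged, scales values
  s3 <- smooth_series(mk_minute_ts(3.7 * v))
  r3 <- find_response(s3, T0 + 120 * 60, search_window = c(-60, 240))
  expect_equal(r3$fwhm_duration, r$fwhm_duration)
  expect_equal(r3$time_to_peak, r$time_to_peak)
  expect_equal(r3$time_to_p90, r$time_to_p90)
  expect_equal(r3$peak_value, 3.7 * r$peak_value)
  expect_equal(r3$average_in_fwhm, 3.7 * r$average_in_fwhm)

  # p90 invariants
  expect_lte(r$value_p90, r$peak_value)
  expect_lte(r$time_to_p90, r$time_to_peak)
})

test_that("peak ties resolve to the earliest maximum", {
  v <- numeric(100)
  v[c(40, 60)] <- 1
  v[41:59] <- 0.9
  s <- mk_minute_ts(v)
  attr(s, "smoothed") <- 1
  r <- find_response(s, T0, search_window = c(0, 100))
  expect_equal(r$time_to_peak, 39)
})

test_that("empty windows yield the no-response sentinel", {
  s <- mk_minute_ts(rep(NA_real_, 100))
  attr(s, "smoothed") <- 1
  r <- find_response(s, T0, search_window = c(0, 50))
  expect_false(r$found)
  expect_true(is.na(r$peak_value))
})

test_that("lights-off profile normalizes to peak 1 and finds the ramp peak", {
  sched <- light_schedule()
  start <- as.POSIXct("2023-01-05 18:00:00", tz = "UTC")  # lights-off
  ramp <- function(noise = 0) {
    m <- 1:720
    pmax(0.01, 0.01 + 0.14 * ifelse(m <= 400, m / 400, (720 - m) / 320) +
                noise * rnorm(720, 0, 0.002))
  }
  # three identical dark periods embedded in 3 days of low daytime activity
  one_day <- c(ramp(), rep(0.01, 720))
  a <- mk_minute_ts(rep(one_day, 3), start = start, schedule = sched)
  prof <- lights_off_profile(a, sched)
  expect_identical(prof$n_periods, 3L)
  expect_equal(max(prof$trace), 1)
  expect_lte(abs(prof$time_to_peak - 400), 2)
  expect_lte(prof$time_to_p90, prof$time_to_peak)

  # identical weeks: averaged trace equals a single-period trace
  a1 <- mk_minute_ts(one_day, start = start, schedule = sched)
  prof1 <- lights_off_profile(a1, sched)
  expect_equal(prof$trace, prof1$trace)

  # an all-zero dark period cannot be normalized
  z <- mk_minute_ts(rep(0, 1440), start = start, schedule = sched)
  expect_error(lights_off_profile(z, sched), "cannot normalize")
})

test_that("response aggregation reports grouped means and dispersions", {
  df <- data.frame(week = c(1, 1, 2), peak_value = c(0.2, 0.2, 0.4),
                   time_to_peak = c(30, 40, 50), fwhm_duration = c(60, 70, 80),
                   average_in_fwhm = c(0.1, 0.12, 0.2),
                   value_p90 = c(0.18, 0.18, 0.35),
                   time_to_p90 = c(20, 25, 45), found = TRUE)
  ag <- aggregate_responses(df, "week")
  expect_identical(nrow(ag), 2L)
  expect_equal(ag$n, c(2L, 1L))
  expect_equal(ag$peak_value_mean, c(0.2, 0.4))
  expect_equal(ag$peak_value_sd[1], 0)       # identical repeats
  expect_equal(ag$fwhm_duration_mean, c(65, 80))
  # single-metric group: mean equals the metric
  expect_equal(ag$time_to_peak_mean[2], 50)
})
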