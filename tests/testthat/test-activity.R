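sched <- light_schedule()

test_that("minute binning arithmetic and missing-bin policy", {
  # two fully sampled minutes: 240 pair slots per electrode per minute
  ev <- matrix(FALSE, 480, 12)
  set.seed(1)
  pick <- cbind(sample(241:480, 288, replace = TRUE),
                sample(12, 288, replace = TRUE))
  pick <- pick[!duplicated(pick), , drop = FALSE]
  # top up to exactly 288 distinct events in minute 2
  while (nrow(pick) < 288) {
    extra <- cbind(sample(241:480, 288 - nrow(pick), replace = TRUE),
                   sample(12, 288 - nrow(pick), replace = TRUE))
    pick <- rbind(pick, extra)
    pick <- pick[!duplicated(pick), , drop = FALSE]
  }
  ev[pick] <- TRUE
  acts <- mk_acts(ev, start = T0)   # pair timestamps T0+0.25 .. T0+120
  a <- bin_activity(acts, 60)
  expect_identical(nrow(a), 2L)
  expect_identical(a$valid_slots, c(2880L, 2880L))
  expect_equal(a$activity[2], 288 / 2880)
  expect_equal(a$activity[2], 0.1)

  # zero events give exactly zero, not missing
  a0 <- bin_activity(mk_acts(matrix(FALSE, 480, 12)), 60)
  expect_identical(a0$activity, c(0, 0))

  # a bin with no valid slots is missing, not zero
  ev2 <- matrix(TRUE, 480, 12)
  acts2 <- cagepulse:::activation_series(
    "T", T0 + (seq_len(480) - 1) * 0.25, ev2 & FALSE,
    rbind(matrix(TRUE, 240, 12), matrix(FALSE, 240, 12)), rep(0.2, 12))
  a2 <- bin_activity(acts2, 60)
  expect_identical(a2$valid_slots[2], 0L)
  expect_true(is.na(a2$activity[2]))
})

test_that("binning equals brute-force counting on random event matrices", {
  set.seed(9)
  for (rep in 1:5) {
    np <- sample(100:600, 1)
    ev <- matrix(runif(np * 12) < 0.2, np, 12)
    va <- matrix(runif(np * 12) < 0.9, np, 12)
    ev <- ev & va
    acts <- cagepulse:::activation_series("T", T0 + seq_len(np) * 7.3,
                                          ev, va, rep(0.2, 12))
    a <- bin_activity(acts, 60)
    ref <- naive_bin(acts, 60)
    expect_identical(a$events, ref$events)
    expect_identical(a$valid_slots, ref$slots)
  }
})

test_that("bins carry phase, week and cycle-day labels", {
  # 1-min bins across the lights-on boundary
  np <- 480
  acts <- mk_acts(matrix(FALSE, np, 12),
                  start = as.POSIXct("2023-01-09 05:59:00", tz = "UTC"))
  cal <- weekly_calendar("2023-01-05 10:00:00", 2)
  a <- bin_activity(acts, 60, sched, cal)
  expect_identical(a$phase[a$tod_min < 360], rep("night", sum(a$tod_min < 360)))
  expect_identical(a$phase[a$tod_min >= 360], rep("day", sum(a$tod_min >= 360)))
  # Jan 9 is 4 days after the Thursday cage-change: weighing day, cycle day 4
  expect_identical(unique(a$week), 1L)
  expect_identical(unique(a$cycle_day), 4)
})

test_that("floor areas partition activity and reconstruct the global series", {
  layout <- electrode_layout()
  set.seed(3)
  np <- 700
  ev <- matrix(runif(np * 12) < 0.15, np, 12)
  va <- matrix(runif(np * 12) < 0.95, np, 12)
  ev <- ev & va
  acts <- cagepulse:::activation_series("T", T0 + seq_len(np) * 0.25, ev, va,
                                        rep(0.2, 12))
  fas <- spatial_group(acts, layout, 60)

  # slot-weighted mean of the four areas equals the global series
  num <- Reduce(`+`, lapply(fas$areas, function(a) a$events))
  den <- Reduce(`+`, lapply(fas$areas, function(a) a$valid_slots))
  expect_equal(num / den, fas$global$activity, tolerance = 1e-12)

  # events confined to electrodes 1-3 appear only in the front area
  ev2 <- matrix(FALSE, np, 12)
  ev2[, 1:3] <- runif(np * 3) < 0.3
  acts2 <- cagepulse:::activation_series("T", T0 + seq_len(np) * 0.25, ev2,
                                         matrix(TRUE, np, 12), rep(0.2, 12))
  fas2 <- spatial_group(acts2, layout, 60)
  expect_gt(sum(fas2$areas$front$events), 0)
  expect_identical(sum(fas2$areas$middle_front$events), 0L)
  expect_identical(sum(fas2$areas$rear$events), 0L)

  # uniform events give four identical series
  ev3 <- matrix(TRUE, np, 12)
  acts3 <- cagepulse:::activation_series("T", T0 + seq_len(np) * 0.25, ev3,
                                         matrix(TRUE, np, 12), rep(0.2, 12))
  fas3 <- spatial_group(acts3, electrode_layout(), 60)
  for (nm in names(fas3$areas)) {
    expect_identical(fas3$areas[[nm]]$activity, fas3$areas$front$activity)
  }
})

test_that("normalization gives unit window means and flags dead windows", {
  cal <- weekly_calendar("2023-01-05 10:00:00", 3)
  # constant series: every bin becomes 1
  a <- mk_minute_ts(rep(0.05, 2 * 1440), start = T0, calendar = cal)
  n <- normalize_activity(a)
  expect_equal(unique(n$activity), 1)

  # two-bin window: [0.1, 0.3] -> [0.5, 1.5]
  b <- mk_minute_ts(c(0.1, 0.3), start = T0, calendar = cal)
  nb <- normalize_activity(b)
  expect_equal(nb$activity, c(0.5, 1.5))

  # random series: every cycle mean is exactly 1
  set.seed(4)
  cc <- mk_minute_ts(runif(14 * 1440, 0, 0.3), start = T0, calendar = cal)
  ncc <- normalize_activity(cc)
  for (w in unique(ncc$week)) {
    expect_equal(mean(ncc$activity[ncc$week == w], na.rm = TRUE), 1,
                 tolerance = 1e-12)
  }

  # an all-zero window cannot be normalized
  dead <- mk_minute_ts(rep(0, 1440), start = T0, calendar = cal)
  nd <- suppressWarnings(normalize_activity(dead))
  expect_true(all(is.na(nd$activity)))
  expect_identical(attr(nd, "non_normalizable"), "1")
})

test_that("day/night fractions are percentages that sum to 100", {
  # one full day: 30 events during day bins, 70 during night bins
  vals <- numeric(1440)
  a <- mk_minute_ts(vals, start = T0, schedule = sched)
  a$events <- 0L
  a$events[which(a$phase == "day")[1:30]] <- 1L
  a$events[which(a$phase == "night")[1:70]] <- 1L
  a$activity <- a$events / a$valid_slots
  fr <- activity_fraction(a, "phase")
  expect_equal(fr$day_pct, 30)
  expect_equal(fr$night_pct, 70)
  expect_equal(fr$day_pct + fr$night_pct, 100, tolerance = 1e-9)

  # all activity in one phase
  b <- mk_minute_ts(numeric(1440), start = T0, schedule = sched)
  b$events <- ifelse(b$phase == "night", 2L, 0L)
  frb <- activity_fraction(b, "phase")
  expect_equal(frb$night_pct, 100)
  expect_equal(frb$day_pct, 0)

  # a day with no events has undefined fractions
  z <- mk_minute_ts(numeric(1440), start = T0, schedule = sched)
  z$events <- 0L
  expect_true(is.na(activity_fraction(z, "phase")$day_pct))
})
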