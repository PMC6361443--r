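ps <- preset_scenarios()

test_that("simulation is deterministic under a seed and varies across seeds", {
  a <- simulate_cage(ps[["baseline"]], duration = 300, seed = 5)
  b <- simulate_cage(ps[["baseline"]], duration = 300, seed = 5)
  expect_identical(a$signal$values, b$signal$values)
  expect_identical(a$truth$sigma, b$truth$sigma)
  d <- simulate_cage(ps[["baseline"]], duration = 300, seed = 6)
  expect_false(identical(a$signal$values, d$signal$values))
})

test_that("zero-mouse cages are pure baseline plus noise", {
  sim <- simulate_cage(ps[["no-intervention"]], duration = 1800, seed = 8,
                       n_mice = 0)
  v <- sim$signal$values
  # per-electrode mean ~ baseline, sd ~ sigma
  expect_equal(unname(colMeans(v)), sim$truth$baseline, tolerance = 0.01)
  expect_equal(unname(apply(v, 2, sd)), unname(sim$truth$sigma),
               tolerance = 0.05)
  # and the detected event rate matches the Gaussian-difference tail
  acts <- detect_activations(sim$signal, threshold = 4 * sim$truth$sigma)
  p <- 2 * pnorm(-4 / sqrt(2))
  np <- sum(acts$n_valid_pairs)
  expect_lt(abs(sum(acts$events) / np - p), 3 * sqrt(p * (1 - p) / np))
})

test_that("binned activity rises with the simulated intensity (common seeds)", {
  acts_for <- function(scale, seed) {
    sc <- ps[["no-intervention"]]
    sc$lambda_scale <- scale
    sim <- simulate_cage(sc, duration = 6 * 3600, seed = seed)  # first 6 h
    acts <- detect_activations(sim$signal, threshold = 4 * sim$truth$sigma,
                               assume_clean = TRUE)
    mean(bin_activity(acts, 60)$activity, na.rm = TRUE)
  }
  # night-time λ doubled: night activity strictly increases, paired seeds
  for (seed in c(2, 3)) {
    lo <- acts_for(1, seed)
    hi <- acts_for(2, seed)
    expect_gt(hi, lo)
  }
  # monotone over a gain ladder
  ladder <- vapply(c(0.5, 1, 2, 4), acts_for, numeric(1), seed = 4)
  expect_true(all(diff(ladder) > 0))
})

test_that("mice confined over the front row put >=90% of events there", {
  sc <- ps[["no-intervention"]]
  sc$bounds <- c(0, 20, 2.625, 3.625)   # strip over row-1 electrode centers
  sc$lambda_scale <- 6                  # keep them moving
  sim <- simulate_cage(sc, duration = 2 * 3600, seed = 8)
  acts <- detect_activations(sim$signal, threshold = 4 * sim$truth$sigma,
                             assume_clean = TRUE)
  af <- activity_fraction(spatial_group(acts, electrode_layout(), 60), "area")
  expect_gt(af$fraction_pct[af$area == "front"], 90)
})

test_that("daily chunking reproduces the monolithic simulation exactly", {
  run <- run_scenario(ps[["baseline"]], days = 2, seed = 77)
  sim <- simulate_cage(ps[["baseline"]], duration = 2 * 86400, seed = 77)
  acts <- detect_activations(sim$signal, threshold = run$theta,
                             assume_clean = TRUE)
  a2 <- bin_activity(acts, 60, light_schedule(), run$calendar)
  expect_identical(run$activity$events, a2$events)
  expect_identical(run$activity$activity, a2$activity)
})

test_that("event injection composes gains and labels the calendar", {
  sc <- ps[["no-intervention"]]
  # no events: hazard equals the bare circadian intensity
  ev0 <- cagepulse:::expand_events(sc, 1)
  i0 <- cagepulse:::minute_intensity(sc, sc$start, 1440, ev0)
  expect_equal(i0$gain, rep(1, 1440))

  # one cage-change with a ~3 h kernel elevates λ for hours, then returns
  sc2 <- inject_events(sc,
    calendar = data.frame(type = "cage_change",
                          time = as.POSIXct("2023-01-05 10:00:00",
                                            tz = "UTC")),
    kernels = list(cage_change = event_kernel(peak_gain = 3, decay = 180)))
  ev2 <- cagepulse:::expand_events(sc2, 1)
  i2 <- cagepulse:::minute_intensity(sc2, sc2$start, 1440, ev2)
  expect_equal(i2$gain[1:600], rep(1, 600))        # before the event
  expect_gt(i2$gain[615], 2.5)                     # shortly after
  expect_lt(i2$gain[1440], 1.1)                    # far away: back to ~1
  expect_true(all(i2$hazard >= i0$hazard - 1e-15))

  # overlapping identical events warn
  dup <- data.frame(type = c("cage_change", "cage_change"),
                    time = rep(as.POSIXct("2023-01-05 10:00:00", tz = "UTC"),
                               2))
  expect_warning(inject_events(sc, calendar = dup), "composed")

  # weekly Thursday cage-change + Monday weighing over 4 weeks: 8 events,
  # with weighing on cycle day 4
  ev <- cagepulse:::expand_events(ps[["baseline"]], 28)
  expect_identical(nrow(ev), 8L)
  cal <- intervention_calendar(ev)
  wday <- as.numeric(cagepulse:::utc_date(ev$time[ev$type == "weighing"][1]) -
                     cagepulse:::anchor_days(cal)[1])
  expect_identical(wday, 4)
})

test_that("presets encode the intended study designs", {
  expect_setequal(names(ps),
                  c("baseline", "CNR-like", "KI-like", "JAX-like",
                    "male-KI-like", "biweekly", "no-intervention"))
  expect_identical(ps[["KI-like"]]$profile$time_to_peak, 440)
  expect_identical(ps[["biweekly"]]$calendar_spec$cage_change$every_days, 14)
  expect_gt(ps[["male-KI-like"]]$kernels$cage_change$carry_gain, 0)
  # bi-weekly design yields 14-day cycles
  cal <- intervention_calendar(cagepulse:::expand_events(ps[["biweekly"]], 28))
  expect_equal(cycles(cal)$days, 14)
  # circadian templates are positive and nocturnally biased
  for (nm in names(ps)) {
    lam <- lambda_at(ps[[nm]]$profile, 0:1439)
    expect_true(all(lam > 0))
    night <- c(0:359, 1080:1439) + 1
    expect_gt(mean(lam[night]), mean(lam[-night]))
  }
})
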