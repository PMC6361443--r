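test_that("signal CSV round trip preserves the data region", {
  sig <- rand_signal(50, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal(sig, f)
  back <- read_signal(f)
  expect_equal(back$values, sig$values, tolerance = 1e-9)
  expect_equal(as.numeric(back$timestamps), as.numeric(sig$timestamps),
               tolerance = 5e-4)
  expect_identical(back$cage_id, sig$cage_id)

  # writing the re-read table reproduces the file byte for byte
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_signal(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("degenerate tables write correctly", {
  empty <- signal_table(matrix(numeric(0), 0, 12),
                        as.POSIXct(character(0), tz = "UTC"), "E")
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal(empty, f)
  expect_identical(length(readLines(f)), 1L)  # header only

  one <- signal_table(matrix(1:12, 1, 12), T0, "O")
  write_signal(one, f)
  lines <- readLines(f)
  expect_identical(length(lines), 2L)
  expect_identical(length(strsplit(lines[2], ",")[[1]]), 14L)
})

test_that("electrode columns are normalized to index order", {
  sig <- rand_signal(5, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal(sig, f)
  dt <- data.table::fread(f)
  perm <- c("cage_id", "timestamp", "e07", "e02", sprintf("e%02d", c(1, 3:6, 8:12)))
  data.table::setcolorder(dt, perm)
  data.table::fwrite(dt, f)
  back <- read_signal(f)
  expect_identical(colnames(back$values), sprintf("e%02d", 1:12))
  expect_equal(back$values, sig$values, tolerance = 1e-9)
})

test_that("schema and timestamp validation is total", {
  sig <- rand_signal(6, seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_signal(sig, f)

  # missing electrode column is fatal
  dt <- data.table::fread(f)
  dt[["e05"]] <- NULL
  data.table::fwrite(dt, f)
  expect_error(read_signal(f), "e05")

  # unparseable timestamps are rejected and counted
  write_signal(sig, f)
  dt <- data.table::fread(f, colClasses = list(character = "timestamp"))
  dt$timestamp[3] <- "not-a-time"
  data.table::fwrite(dt, f)
  expect_message(back <- read_signal(f), "rejected 1")
  expect_identical(nrow(back$values), 5L)
  expect_identical(attr(back, "n_rejected"), 1L)

  # non-monotonic timestamps are fatal, with the row index
  write_signal(sig, f)
  dt <- data.table::fread(f, colClasses = list(character = "timestamp"))
  dt$timestamp[4] <- dt$timestamp[2]
  data.table::fwrite(dt, f)
  expect_error(read_signal(f), "row 4")
})

test_that("non-finite readings are flagged, not dropped", {
  v <- matrix(rnorm(36), 3, 12)
  v[2, 5] <- NA
  sig <- signal_table(v, T0 + (0:2) * 0.25)
  expect_identical(sig$flagged_rows, 2L)
  expect_identical(nrow(sig$values), 3L)
})

test_that("study config defaults, cycles and validation behave", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("light_schedule:", "  lights_on: '06:00'",
               "  lights_off: '18:00'"), f)
  cfg <- load_study_config(f)
  expect_identical(nrow(cfg$calendar$events), 0L)
  expect_true(any(grepl("calendar", cfg$provenance$defaults_applied)))

  # 4 weekly anchors delimit 3 complete cycles
  writeLines(c("calendar:", "  weekly:",
               "    start: 2023-01-05T10:00:00+00:00",
               "    n_cycles: 4"), f)
  cfg <- load_study_config(f)
  anchors <- cfg$calendar$events[cfg$calendar$events$type == "cage_change", ]
  expect_identical(nrow(anchors), 4L)
  cy <- cycles(cfg$calendar)
  expect_identical(nrow(cy), 3L)
  expect_equal(cy$days, rep(7, 3))

  # bi-weekly cage change gives 14-day cycles
  writeLines(c("calendar:", "  weekly:",
               "    start: 2023-01-05T10:00:00+00:00",
               "    n_cycles: 3", "    every_days: 14",
               "    weighing_offset_days: null"), f)
  cfg <- load_study_config(f)
  expect_equal(cycles(cfg$calendar)$days, rep(14, 2))

  # invalid clock time is a validation error
  writeLines(c("light_schedule:", "  lights_on: '26:00'",
               "  lights_off: '18:00'"), f)
  expect_error(load_study_config(f), "clock time")

  # events outside the recording range warn but are retained
  writeLines(c("calendar:", "  events:",
               "    - type: cage_change",
               "      time: 2023-02-01T10:00:00+00:00",
               "recording:", "  start: 2023-01-01", "  end: 2023-01-10"), f)
  expect_warning(cfg <- load_study_config(f), "outside")
  expect_identical(nrow(cfg$calendar$events), 1L)
})
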