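# Shared fixtures and independent brute-force oracles.

T0 <- as.POSIXct("2023-01-05 00:00:00", tz = "UTC")

# random signal table; optionally with NA rows and timing gaps
rand_signal <- function(n, seed, with_na = FALSE, with_gaps = FALSE,
                        sd = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * 12, sd = sd), n, 12)
  if (with_na) {
    bad <- sample(n, max(1, n %/% 20))
    v[cbind(bad, sample(12, length(bad), replace = TRUE))] <- NA_real_
  }
  ts <- T0 + (0:(n - 1)) * 0.25
  if (with_gaps) {
    jump <- sort(sample(2:(n - 1), max(1, n %/% 30)))
    off <- numeric(n)
    off[jump] <- runif(length(jump), 0.5, 5)
    ts <- ts + cumsum(off)
  }
  signal_table(v, ts, cage_id = paste0("R", seed))
}

# literal definition of the activation metric: loop over electrodes and pairs
naive_detect <- function(signal, theta, max_gap = 0.5) {
  n <- nrow(signal$values)
  theta <- rep_len(theta, 12)
  ev <- matrix(FALSE, n - 1, 12)
  va <- matrix(FALSE, n - 1, 12)
  tt <- as.numeric(signal$timestamps)
  for (e in 1:12) {
    for (i in 2:n) {
      a <- signal$values[i - 1, e]
      b <- signal$values[i, e]
      if (is.finite(a) && is.finite(b) && (tt[i] - tt[i - 1]) <= max_gap + 1e-9) {
        va[i - 1, e] <- TRUE
        ev[i - 1, e] <- abs(b - a) > theta[e]
      }
    }
  }
  list(events = ev, valid = va)
}

# brute-force per-bin counting
naive_bin <- function(acts, bin_width) {
  pt <- as.numeric(acts$pair_timestamps)
  origin <- as.numeric(trunc(acts$pair_timestamps[1], units = "days"))
  idx <- floor((pt - origin) / bin_width)
  valid <- if (is.null(acts$valid)) {
    matrix(TRUE, nrow(acts$events), 12)
  } else acts$valid
  out <- NULL
  for (b in seq(min(idx), max(idx))) {
    rows <- which(idx == b)
    ev <- 0L; sl <- 0L
    for (r in rows) for (e in 1:12) {
      if (valid[r, e]) {
        sl <- sl + 1L
        if (acts$events[r, e]) ev <- ev + 1L
      }
    }
    out <- rbind(out, data.frame(bin = b, events = ev, slots = sl))
  }
  out
}

# literal S1-style block rule: runs above half-peak, iterative merging of
# gaps shorter than merge_gap, pick the run holding the max, return extent
naive_fwhm <- function(v, merge_gap = 5) {
  ipk <- which.max(v)
  half <- v[ipk] / 2
  above <- !is.na(v) & v > half
  runs <- list()
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  merged <- TRUE
  while (merged && length(runs) > 1) {
    merged <- FALSE
    for (k in seq_len(length(runs) - 1)) {
      gap <- runs[[k + 1]][1] - runs[[k]][2] - 1
      if (gap < merge_gap) {
        runs[[k]] <- c(runs[[k]][1], runs[[k + 1]][2])
        runs[[k + 1]] <- NULL
        merged <- TRUE
        break
      }
    }
  }
  blk <- Filter(function(r) r[1] <= ipk && ipk <= r[2], runs)[[1]]
  list(start = blk[1], end = blk[2], duration = blk[2] - blk[1] + 1,
       peak = v[ipk])
}

# build a 1-min activity_ts from a numeric vector
mk_minute_ts <- function(values, start = T0, cage = "T",
                         schedule = NULL, calendar = NULL) {
  n <- length(values)
  bs <- start + (seq_len(n) - 1) * 60
  df <- data.frame(
    bin_start = bs, date = as.Date(as.POSIXlt(bs, tz = "UTC")),
    tod_min = (as.numeric(bs) %% 86400) / 60,
    phase = if (is.null(schedule)) NA_character_ else {
      m <- (as.numeric(bs) %% 86400) / 60
      ifelse(m >= schedule$on_min & m < schedule$off_min, "day", "night")
    },
    week = NA_integer_, cycle_day = NA_integer_,
    events = NA_integer_, valid_slots = 2880L, activity = values)
  if (!is.null(calendar)) {
    ad <- cagepulse:::anchor_days(calendar)
    wk <- findInterval(as.numeric(df$date), as.numeric(ad))
    df$week <- ifelse(wk >= 1, wk, NA_integer_)
    df$cycle_day <- ifelse(wk >= 1,
                           as.numeric(df$date) - as.numeric(ad[pmax(wk, 1)]),
                           NA_integer_)
  }
  cagepulse:::as_activity_ts(df, cage, 60)
}

# activation series with an explicit event pattern (all pairs valid)
mk_acts <- function(events, start = T0, cage = "T") {
  np <- nrow(events)
  cagepulse:::activation_series(cage, start + (seq_len(np) - 1) * 0.25,
                                events, matrix(TRUE, np, 12), rep(0.2, 12))
}

# run the CLI capturing console output; returns the exit status
cli_quiet <- function(args) {
  utils::capture.output(status <- suppressMessages(cagepulse_cli(args)))
  status
}
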