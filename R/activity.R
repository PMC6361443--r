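#' Bin activation events into an activity time series
#'
#' Activity in a bin is the fraction of valid electrode-sample-pair slots in
#' the bin whose first difference exceeded the threshold:
#' `events / valid_slots`, pooled over the selected electrodes, bounded in
#' \[0, 1\]. A pair belongs to the bin containing its *later* sample, so with
#' continuous 4 Hz sampling a 1-min bin holds 240 pair slots per electrode
#' (2880 over all 12). Bins with zero valid slots are marked missing (`NA`),
#' never zero. Each bin is labelled with its light phase (day/night), its
#' calendar date, and — when a calendar is given — the week index and the
#' weekday of the cage-change cycle (day 0 = calendar day of the cage-change).
#'
#' @param acts an `activation_series` from [detect_activations()].
#' @param bin_width bin width in seconds (default 60; must be at least the
#'   sampling period).
#' @param schedule optional [light_schedule()] for day/night labels.
#' @param calendar optional [intervention_calendar()] for week / cycle-day
#'   labels.
#' @param electrodes electrode subset to pool (default all 12).
#' @return A `data.frame` of class `activity_ts` with columns `bin_start`
#'   (POSIXct), `date`, `tod_min` (minute of day of the bin start), `phase`,
#'   `week`, `cycle_day`, `events`, `valid_slots`, `activity`. Attributes:
#'   `cage_id`, `bin_width`, `electrodes`.
#' @export
bin_activity <- function(acts, bin_width = 60, schedule = NULL,
                         calendar = NULL, electrodes = 1:12) {
  stopifnot(inherits(acts, "activation_series"))
  if (bin_width < 0.25) stop("bin_width must be >= the sampling period")
  np <- nrow(acts$events)
  if (np == 0L) {
    out <- data.frame(bin_start = as.POSIXct(character(0), tz = "UTC"),
                      date = as.Date(character(0)), tod_min = numeric(0),
                      phase = character(0), week = integer(0),
                      cycle_day = integer(0), events = integer(0),
                      valid_slots = integer(0), activity = numeric(0))
    return(as_activity_ts(out, acts$cage_id, bin_width, electrodes))
  }
  pt <- as.numeric(acts$pair_timestamps)
  origin <- as.numeric(trunc(acts$pair_timestamps[1], units = "days"))
  idx <- floor((pt - origin) / bin_width)
  lev <- seq(min(idx), max(idx))
  ev <- rowSums(acts$events[, electrodes, drop = FALSE])
  rs_e <- rowsum(ev, idx)
  pos <- match(as.numeric(rownames(rs_e)), lev)
  events <- integer(length(lev)); events[pos] <- as.integer(rs_e)
  slots <- integer(length(lev))
  if (is.null(acts$valid)) {
    slots[pos] <- as.integer(rowsum(rep(1L, np), idx)) * length(electrodes)
  } else {
    va <- rowSums(acts$valid[, electrodes, drop = FALSE])
    rs_v <- rowsum(va, idx)
    slots[pos] <- as.integer(rs_v)
  }
  bin_start <- .POSIXct(origin + lev * bin_width, tz = "UTC")
  activity <- ifelse(slots > 0L, events / pmax(slots, 1L), NA_real_)

  out <- data.frame(bin_start = bin_start, date = utc_date(bin_start),
                    tod_min = minute_of_day(bin_start),
                    phase = if (is.null(schedule)) NA_character_
                            else phase_at(bin_start, schedule),
                    week = NA_integer_, cycle_day = NA_integer_,
                    events = events, valid_slots = slots, activity = activity)
  if (!is.null(calendar)) {
    ad <- anchor_days(calendar)
    if (length(ad)) {
      wk <- findInterval(as.numeric(out$date), as.numeric(ad))
      out$week <- ifelse(wk >= 1L, wk, NA_integer_)
      out$cycle_day <- ifelse(wk >= 1L,
                              as.numeric(out$date) - as.numeric(ad[pmax(wk, 1L)]),
                              NA_integer_)
    }
  }
  as_activity_ts(out, acts$cage_id, bin_width, electrodes)
}

#' @noRd
as_activity_ts <- function(df, cage_id, bin_width, electrodes = 1:12) {
  attr(df, "cage_id") <- cage_id
  attr(df, "bin_width") <- bin_width
  attr(df, "electrodes") <- electrodes
  class(df) <- c("activity_ts", "data.frame")
  df
}

#' @export
print.activity_ts <- function(x, ...) {
  cat("<activity_ts> cage ", attr(x, "cage_id"), ": ", nrow(x), " bins of ",
      attr(x, "bin_width"), " s; ", sum(is.na(x$activity)),
      " missing\n", sep = "")
  print(head(as.data.frame(x), 6), ...)
  invisible(x)
}

#' @export
plot.activity_ts <- function(x, ...) {
  graphics::plot(x$bin_start, x$activity, type = "l",
                 xlab = "time", ylab = "activity (fraction of slots)", ...)
  invisible(x)
}

#' Decompose activity over the four floor areas
#'
#' Groups the activation data of each row of three electrodes into the four
#' floor areas (front, middle-front, middle-rear, rear) and bins each area
#' separately. The slot-weighted mean of the four area series reconstructs
#' the all-electrode series exactly.
#'
#' @inheritParams bin_activity
#' @param layout an [electrode_layout()].
#' @return Object of class `floor_area_series`: a named list of four
#'   `activity_ts` plus the global series under `$global`.
#' @export
spatial_group <- function(acts, layout = electrode_layout(), bin_width = 60,
                          schedule = NULL, calendar = NULL) {
  areas <- lapply(layout$areas, function(e) {
    bin_activity(acts, bin_width, schedule, calendar, electrodes = e)
  })
  structure(list(areas = areas,
                 global = bin_activity(acts, bin_width, schedule, calendar),
                 layout = layout),
            class = "floor_area_series")
}

#' @export
print.floor_area_series <- function(x, ...) {
  cat("<floor_area_series> areas:", paste(names(x$areas), collapse = ", "),
      "\n")
  invisible(x)
}

#' Normalize activity by its window mean
#'
#' Normalized activity is the binned activity divided by the average activity
#' over a reference window — by default the cage-change cycle the bin belongs
#' to — so that every window has mean 1. Windows whose mean is zero (or that
#' contain no non-missing bin) cannot be normalized; their bins are set
#' missing and the window is reported in the `non_normalizable` attribute.
#'
#' @param series an `activity_ts`.
#' @param window `"cycle"` (group bins by week of the cage-change cycle),
#'   `"all"` (a single window), or a vector/factor with one window label per
#'   bin.
#' @return An `activity_ts` with `activity` replaced by normalized activity
#'   (unit mean per window over non-missing bins).
#' @export
normalize_activity <- function(series, window = "cycle") {
  stopifnot(inherits(series, "activity_ts"))
  w <- if (identical(window, "cycle")) {
    series$week
  } else if (identical(window, "all")) {
    rep(1L, nrow(series))
  } else {
    if (length(window) != nrow(series)) stop("window labels must match bins")
    window
  }
  out <- series
  out$activity <- NA_real_
  bad <- character(0)
  for (g in unique(w[!is.na(w)])) {
    i <- which(!is.na(w) & w == g)
    m <- mean(series$activity[i], na.rm = TRUE)
    if (!is.finite(m) || m <= 0) {
      bad <- c(bad, as.character(g))
    } else {
      out$activity[i] <- series$activity[i] / m
    }
  }
  attr(out, "normalized") <- TRUE
  attr(out, "non_normalizable") <- bad
  out
}

#' Fraction of activity per time window or floor area
#'
#' The percentage of total activity allocated to a partition of each 24 h day
#' (default: day vs night phase). Fractions are event-count weighted and sum
#' to 100 per day wherever the day has any activity; days with no events
#' yield `NA` fractions.
#'
#' @param series an `activity_ts` with phase labels (see [bin_activity()]),
#'   or a `floor_area_series` for the per-area variant.
#' @param by partition: `"phase"` (day/night; `activity_ts` input) or
#'   `"area"` (`floor_area_series` input).
#' @param per `"date"` for one row per calendar day, or `"all"` for a single
#'   overall breakdown.
#' @return `data.frame` with the partition fractions in percent.
#' @export
activity_fraction <- function(series, by = c("phase", "area"), per = "date") {
  by <- match.arg(by)
  if (by == "area") {
    stopifnot(inherits(series, "floor_area_series"))
    ev <- vapply(series$areas, function(a) sum(a$events, na.rm = TRUE),
                 numeric(1))
    tot <- sum(ev)
    return(data.frame(area = names(ev),
                      fraction_pct = if (tot > 0) 100 * ev / tot
                                     else NA_real_))
  }
  stopifnot(inherits(series, "activity_ts"))
  if (all(is.na(series$phase))) stop("series has no phase labels")
  if (identical(per, "all")) {
    dsum <- sum(series$events[series$phase == "day"], na.rm = TRUE)
    nsum <- sum(series$events[series$phase == "night"], na.rm = TRUE)
    tot <- dsum + nsum
    return(data.frame(day_pct = if (tot > 0) 100 * dsum / tot else NA_real_,
                      night_pct = if (tot > 0) 100 * nsum / tot else NA_real_))
  }
  dates <- sort(unique(series$date))
  res <- lapply(dates, function(d) {
    s <- series[series$date == d, ]
    dsum <- sum(s$events[s$phase == "day"], na.rm = TRUE)
    nsum <- sum(s$events[s$phase == "night"], na.rm = TRUE)
    tot <- dsum + nsum
    data.frame(date = d,
               day_pct = if (tot > 0) 100 * dsum / tot else NA_real_,
               night_pct = if (tot > 0) 100 * nsum / tot else NA_real_,
               n_bins = nrow(s),
               n_missing = sum(is.na(s$activity)))
  })
  do.call(rbind, res)
}

#' Write / read the tidy activity CSV
#'
#' Tidy export dialect: columns `cage_id, bin_start, bin_width_s, activity,
#' valid_slots, phase, week, cycle_day` (one row per bin; `bin_start`
#' ISO-8601 UTC). Event counts are recovered on read as
#' `activity * valid_slots`.
#'
#' @param series an `activity_ts`.
#' @param path file path.
#' @return `path` invisibly (write); an `activity_ts` (read).
#' @export
write_activity <- function(series, path) {
  stopifnot(inherits(series, "activity_ts"))
  dt <- data.table::data.table(
    cage_id = attr(series, "cage_id"),
    bin_start = format(series$bin_start, "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC"),
    bin_width_s = attr(series, "bin_width"),
    activity = series$activity,
    valid_slots = series$valid_slots,
    phase = series$phase,
    week = series$week,
    cycle_day = series$cycle_day)
  data.table::fwrite(dt, path, showProgress = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  if (!file.exists(path)) stop("activity file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = c("bin_start",
                                                                "phase")),
                          showProgress = FALSE)
  bs <- as.POSIXct(dt$bin_start, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  ev <- ifelse(is.na(dt$activity), 0L,
               as.integer(round(dt$activity * dt$valid_slots)))
  out <- data.frame(bin_start = bs, date = utc_date(bs),
                    tod_min = minute_of_day(bs),
                    phase = ifelse(dt$phase == "", NA_character_, dt$phase),
                    week = dt$week, cycle_day = dt$cycle_day,
                    events = ev, valid_slots = dt$valid_slots,
                    activity = dt$activity)
  as_activity_ts(out, as.character(dt$cage_id[1]), dt$bin_width_s[1])
}
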