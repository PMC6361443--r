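#' Light schedule of the vivarium
#'
#' Instant (step) light transitions with a 24 h period. The default is the
#' standard 12 h on / 12 h off cycle; lights-on marks day break, lights-off
#' marks night onset (the dark cycle is 720 min under the default).
#'
#' @param lights_on,lights_off clock times `"HH:MM"` (UTC).
#' @return Object of class `light_schedule` with on/off minutes-of-day.
#' @export
light_schedule <- function(lights_on = "06:00", lights_off = "18:00") {
  on <- clock_to_minutes(lights_on)
  off <- clock_to_minutes(lights_off)
  if (on == off) stop("lights_on and lights_off must differ")
  structure(list(lights_on = lights_on, lights_off = lights_off,
                 on_min = on, off_min = off, period_min = 1440),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat("<light_schedule> on ", x$lights_on, ", off ", x$lights_off,
      " (UTC), period 24 h\n", sep = "")
  invisible(x)
}

# phase ("day"/"night") of instants under a schedule
#' @noRd
phase_at <- function(t, schedule) {
  m <- minute_of_day(t)
  on <- schedule$on_min
  off <- schedule$off_min
  day <- if (on < off) m >= on & m < off else m >= on | m < off
  ifelse(day, "day", "night")
}

# lights-off instants covering [from, to]
#' @noRd
lights_off_times <- function(schedule, from, to) {
  d0 <- utc_date(from) - 1
  d1 <- utc_date(to) + 1
  days <- seq(d0, d1, by = "day")
  t <- as.POSIXct(as.character(days), tz = "UTC") + schedule$off_min * 60
  t[t >= from & t <= to]
}

#' @noRd
lights_on_times <- function(schedule, from, to) {
  d0 <- utc_date(from) - 1
  d1 <- utc_date(to) + 1
  days <- seq(d0, d1, by = "day")
  t <- as.POSIXct(as.character(days), tz = "UTC") + schedule$on_min * 60
  t[t >= from & t <= to]
}

#' Electrode layout and floor areas
#'
#' The 12 electrodes form a 4 x 3 grid under the cage floor: 4 rows from the
#' front of the cage to the rear, 3 electrodes per row. Each row of three
#' defines one floor area: front, middle-front, middle-rear, rear. Electrode
#' numbering is row-major (1-3 front, 10-12 rear).
#'
#' @param areas optional named list of four integer vectors (length 3 each)
#'   partitioning 1:12; default is one row per area.
#' @return Object of class `electrode_layout` with `grid` (electrode, row,
#'   col) and `areas`.
#' @export
electrode_layout <- function(areas = NULL) {
  grid <- data.frame(electrode = 1:12,
                     row = rep(1:4, each = 3),
                     col = rep(1:3, times = 4))
  if (is.null(areas)) {
    areas <- list(front = 1:3, middle_front = 4:6,
                  middle_rear = 7:9, rear = 10:12)
  }
  if (length(areas) != 4L || !all(lengths(areas) == 3L) ||
      !setequal(unlist(areas), 1:12)) {
    stop("areas must be 4 sets of 3 electrodes partitioning 1:12")
  }
  structure(list(grid = grid, areas = areas), class = "electrode_layout")
}

#' Intervention calendar
#'
#' Time-sorted husbandry events (cage-change, weighing, other). Consecutive
#' events of the anchor type (default `cage_change`) delimit the study's
#' cage-change cycles — the "weeks" of the longitudinal design; day 0 of a
#' cycle is the calendar day of the anchor event.
#'
#' @param events `data.frame` with columns `type` (one of `cage_change`,
#'   `weighing`, `other`) and `time` (`POSIXct` UTC or ISO-8601 string), or
#'   `NULL` for an empty calendar.
#' @param cycle_anchor event type that anchors cycles.
#' @return Object of class `intervention_calendar`.
#' @export
intervention_calendar <- function(events = NULL, cycle_anchor = "cage_change") {
  if (is.null(events) || NROW(events) == 0L) {
    events <- data.frame(type = character(0),
                         time = as.POSIXct(character(0), tz = "UTC"))
  } else {
    events <- as.data.frame(events)
    stopifnot(all(c("type", "time") %in% names(events)))
    if (is.character(events$time)) {
      t <- parse_iso_ms(events$time)
      # allow second-resolution ISO without offset for convenience
      t2 <- as.POSIXct(events$time, tz = "UTC",
                       tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                      "%Y-%m-%d"))
      events$time <- as.POSIXct(ifelse(is.na(t), as.numeric(t2), as.numeric(t)),
                                origin = "1970-01-01", tz = "UTC")
    }
    if (any(is.na(events$time))) stop("unparseable event time in calendar")
    bad <- setdiff(unique(events$type), c("cage_change", "weighing", "other"))
    if (length(bad)) stop("unknown event type(s): ", paste(bad, collapse = ", "))
    events <- events[order(events$time), c("type", "time")]
    rownames(events) <- NULL
  }
  structure(list(events = events, cycle_anchor = cycle_anchor),
            class = "intervention_calendar")
}

#' @export
print.intervention_calendar <- function(x, ...) {
  cat("<intervention_calendar> ", nrow(x$events), " event(s), anchor: ",
      x$cycle_anchor, "\n", sep = "")
  if (nrow(x$events)) print(x$events, ...)
  invisible(x)
}

#' Cycles delimited by anchor events
#'
#' @param calendar an [intervention_calendar()].
#' @return `data.frame` with one row per complete cycle (`start`, `end`,
#'   `days`); `n` anchors give `n - 1` complete cycles.
#' @export
cycles <- function(calendar) {
  a <- calendar$events$time[calendar$events$type == calendar$cycle_anchor]
  if (length(a) < 2L) {
    return(data.frame(start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      days = numeric(0)))
  }
  data.frame(start = a[-length(a)], end = a[-1],
             days = as.numeric(diff(as.numeric(a))) / 86400)
}

# anchor calendar *days* used for week / cycle-day labelling
#' @noRd
anchor_days <- function(calendar) {
  a <- calendar$events$time[calendar$events$type == calendar$cycle_anchor]
  utc_date(a)
}

#' Build a weekly (or n-daily) husbandry calendar
#'
#' Convenience generator mirroring the standard design: a cage-change every
#' `every_days` days plus a weighing/health check offset a few days into each
#' cycle.
#'
#' @param start first cage-change instant (`POSIXct` or parseable string).
#' @param n_cycles number of cage-change events to generate.
#' @param every_days cycle length in days (7 = weekly, 14 = bi-weekly).
#' @param weighing_offset_days offset of the weighing event within the cycle
#'   (default 4: Thursday cage-change, Monday weighing), or `NULL` for none.
#' @return An [intervention_calendar()].
#' @export
weekly_calendar <- function(start, n_cycles, every_days = 7,
                            weighing_offset_days = 4) {
  start <- as.POSIXct(start, tz = "UTC")
  cc <- start + (seq_len(n_cycles) - 1L) * every_days * 86400
  ev <- data.frame(type = rep("cage_change", length(cc)), time = cc)
  if (!is.null(weighing_offset_days)) {
    wg <- cc + weighing_offset_days * 86400
    ev <- rbind(ev, data.frame(type = rep("weighing", length(wg)), time = wg))
  }
  intervention_calendar(ev)
}

#' Assemble a study configuration
#'
#' @param cages `data.frame` with columns `cage_id`, `site`, `sex`,
#'   `n_animals` (default one 5-mouse cage — the standard housing density).
#' @param light_schedule a [light_schedule()].
#' @param calendar an [intervention_calendar()].
#' @param detection list with threshold policy: `policy` (`"mad"` or
#'   `"fixed"`), `k` multiplier, optional `value` for the fixed policy,
#'   `per_electrode` flag.
#' @param recording optional list(start, end) of the recording range.
#' @return Object of class `study_config`.
#' @export
study_config <- function(cages = NULL, light_schedule = cagepulse::light_schedule(),
                         calendar = intervention_calendar(),
                         detection = list(policy = "mad", k = 4,
                                          per_electrode = TRUE),
                         recording = NULL) {
  if (is.null(cages)) {
    cages <- data.frame(cage_id = "cage", site = "site", sex = "female",
                        n_animals = 5L)
  }
  cages <- as.data.frame(cages)
  stopifnot(all(c("cage_id", "n_animals") %in% names(cages)))
  if (anyDuplicated(cages$cage_id)) stop("cage_id values must be unique")
  if (any(cages$n_animals < 0)) stop("n_animals must be >= 0")
  structure(list(cages = cages, light_schedule = light_schedule,
                 calendar = calendar, detection = detection,
                 recording = recording, provenance = list()),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config> ", nrow(x$cages), " cage(s); lights ",
      x$light_schedule$lights_on, "-", x$light_schedule$lights_off, "; ",
      nrow(x$calendar$events), " calendar event(s)\n", sep = "")
  if (length(x$provenance$defaults_applied)) {
    cat("  defaults applied: ",
        paste(x$provenance$defaults_applied, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Load a study configuration from YAML
#'
#' The document is a flat, human-editable YAML file. Recognized top-level
#' keys: `cages` (list of cage_id/site/sex/n_animals records),
#' `light_schedule` (`lights_on`, `lights_off`), `calendar` (either an
#' explicit `events` list of `{type, time}` or a `weekly` block with `start`,
#' `n_cycles`, `every_days`, `weighing_offset_days`), `detection`
#' (`policy`, `k`, `value`), and `recording` (`start`, `end`). Missing blocks
#' get the standard defaults (12/12 schedule, MAD threshold with k = 4, empty
#' calendar); every applied default is recorded in the returned object's
#' `provenance` field. Calendar events outside the declared recording range
#' trigger a warning but are retained.
#'
#' @param path path to the YAML document.
#' @return A validated [study_config()].
#' @export
load_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  defaults <- character(0)

  if (is.null(y$light_schedule)) {
    sched <- light_schedule()
    defaults <- c(defaults, "light_schedule=12/12 (06:00/18:00)")
  } else {
    sched <- light_schedule(y$light_schedule$lights_on %||% "06:00",
                            y$light_schedule$lights_off %||% "18:00")
  }

  if (is.null(y$calendar)) {
    cal <- intervention_calendar()
    defaults <- c(defaults, "calendar=empty")
  } else if (!is.null(y$calendar$weekly)) {
    w <- y$calendar$weekly
    cal <- weekly_calendar(w$start, w$n_cycles %||% 4L,
                           every_days = w$every_days %||% 7,
                           weighing_offset_days = w$weighing_offset_days %||% 4)
  } else {
    ev <- do.call(rbind, lapply(y$calendar$events, function(e) {
      data.frame(type = e$type, time = e$time)
    }))
    cal <- intervention_calendar(ev,
      cycle_anchor = y$calendar$cycle_anchor %||% "cage_change")
  }

  cages <- if (is.null(y$cages)) {
    defaults <- c(defaults, "cages=1x5 mice")
    NULL
  } else {
    do.call(rbind, lapply(y$cages, function(cg) {
      data.frame(cage_id = as.character(cg$cage_id),
                 site = cg$site %||% "site", sex = cg$sex %||% "unknown",
                 n_animals = as.integer(cg$n_animals %||% 5L))
    }))
  }

  det <- y$detection %||% {
    defaults <- c(defaults, "detection=mad,k=4")
    list(policy = "mad", k = 4, per_electrode = TRUE)
  }
  det$k <- det$k %||% 4
  det$policy <- det$policy %||% "mad"
  det$per_electrode <- det$per_electrode %||% TRUE

  rec <- NULL
  if (!is.null(y$recording)) {
    rec <- list(start = as.POSIXct(y$recording$start, tz = "UTC"),
                end = as.POSIXct(y$recording$end, tz = "UTC"))
    outside <- cal$events$time < rec$start | cal$events$time > rec$end
    if (any(outside)) {
      warning(sum(outside), " calendar event(s) outside the recording range; ",
              "retained")
    }
  }

  cfg <- study_config(cages, sched, cal, det, rec)
  cfg$provenance <- list(path = path, defaults_applied = defaults,
                         loaded_at = Sys.time())
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
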