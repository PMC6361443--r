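#' Low-pass smooth a minute activity series
#'
#' Centered 30-min moving average of the minute-based activity time series —
#' the low-pass filter applied before any peak/response detection. At the
#' series edges the window truncates to the available bins; missing bins are
#' excluded from each window's mean (a window with no data stays missing).
#'
#' @param series an `activity_ts` with 1-min bins (or a bare numeric vector
#'   of minute values).
#' @param window window length in minutes (default 30).
#' @return The input with `activity` replaced by its moving average.
#' @export
smooth_series <- function(series, window = 30) {
  x <- if (inherits(series, "activity_ts")) series$activity else as.numeric(series)
  if (length(x) < 2L) stop("series must have at least 2 bins")
  if (inherits(series, "activity_ts") &&
      !isTRUE(all.equal(attr(series, "bin_width"), 60))) {
    stop("smoothing expects 1-min bins (bin_width = 60)")
  }
  sm <- moving_average(x, window)
  if (inherits(series, "activity_ts")) {
    out <- series
    out$activity <- sm
    attr(out, "smoothed") <- window
    out
  } else {
    sm
  }
}

# truncated centered moving average, NA-excluding; window w covers
# i-floor(w/2) .. i+(w-1-floor(w/2))
#' @noRd
moving_average <- function(x, w) {
  n <- length(x)
  L <- floor(w / 2)
  U <- w - 1L - L
  ok <- !is.na(x)
  xs <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xs))
  cn <- c(0, cumsum(ok))
  i <- seq_len(n)
  lo <- pmax(i - L, 1L)
  hi <- pmin(i + U, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- cn[hi + 1L] - cn[lo]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Quantify an event-locked response with the FWHM paradigm
#'
#' Implements the full-width-half-maximum response measure on a smoothed
#' minute series around an event (lights-on, lights-off, cage-change):
#' \enumerate{
#'   \item find the peak of the series within the search window (first
#'     occurrence on ties);
#'   \item find contiguous blocks of minutes whose activity is strictly
#'     larger than half of the peak;
#'   \item merge two blocks separated by fewer than 5 minutes;
#'   \item pick the block containing the maximum; the response duration is
#'     the temporal extent of that block.
#' }
#' `average_in_fwhm` is the mean of the smoothed series over the chosen
#' block. `value_p90` is by default the 90th percentile of the smoothed
#' values in the window (`p90_mode = "window_quantile"`), with `time_to_p90`
#' the first minute at or above it; `p90_mode = "peak_fraction"` instead uses
#' the first crossing of 0.9 x peak.
#'
#' @param smoothed a smoothed 1-min `activity_ts` (see [smooth_series()]).
#' @param event_time event instant (`POSIXct`).
#' @param search_window numeric length-2: minutes relative to the event,
#'   e.g. `c(-180, 180)` for lights-on, `c(0, 720)` for lights-off,
#'   `c(0, 360)` for cage-change.
#' @param merge_gap blocks closer than this many minutes are merged
#'   (default 5; a 4-min gap merges, a 5-min gap does not).
#' @param p90_mode `"window_quantile"` or `"peak_fraction"`.
#' @return Object of class `response_metrics`: `event_type`, `event_time`,
#'   `peak_value`, `time_to_peak` (min), `fwhm_duration` (min),
#'   `fwhm_start`/`fwhm_end` (instants), `average_in_fwhm`, `value_p90`,
#'   `time_to_p90`, `found`. When the window holds no data, `found` is
#'   `FALSE` and the metrics are `NA` (no-response sentinel).
#' @export
find_response <- function(smoothed, event_time, search_window = c(-180, 180),
                          merge_gap = 5, p90_mode = c("window_quantile",
                                                      "peak_fraction"),
                          event_type = "event") {
  stopifnot(inherits(smoothed, "activity_ts"))
  p90_mode <- match.arg(p90_mode)
  bw <- attr(smoothed, "bin_width")
  if (!isTRUE(all.equal(bw, 60))) stop("find_response expects 1-min bins")
  t <- as.numeric(smoothed$bin_start)
  e <- as.numeric(event_time)
  sel <- which(t >= e + search_window[1] * 60 & t < e + search_window[2] * 60)
  v <- smoothed$activity[sel]
  if (!length(sel) || all(is.na(v))) {
    return(response_sentinel(event_type, event_time))
  }
  rel_min <- (t[sel] - e) / 60

  ipk <- which.max(v)                       # first maximum on ties, skips NA
  peak <- v[ipk]
  half <- peak / 2
  supra <- !is.na(v) & v > half             # strict: ties at half excluded
  supra <- merge_blocks(supra, merge_gap)
  blk <- block_of(supra, ipk)

  p90 <- if (p90_mode == "window_quantile") {
    as.numeric(stats::quantile(v, 0.9, na.rm = TRUE, names = FALSE))
  } else {
    0.9 * peak
  }
  i90 <- which(!is.na(v) & v >= p90)[1]

  structure(list(
    event_type = event_type, event_time = event_time,
    peak_value = peak,
    time_to_peak = rel_min[ipk],
    fwhm_duration = (blk[2] - blk[1] + 1),
    fwhm_start = smoothed$bin_start[sel[blk[1]]],
    fwhm_end = smoothed$bin_start[sel[blk[2]]],
    average_in_fwhm = mean(v[blk[1]:blk[2]], na.rm = TRUE),
    value_p90 = p90,
    time_to_p90 = if (is.na(i90)) NA_real_ else rel_min[i90],
    n_bins = length(sel), found = TRUE), class = "response_metrics")
}

#' @noRd
response_sentinel <- function(event_type, event_time) {
  structure(list(event_type = event_type, event_time = event_time,
                 peak_value = NA_real_, time_to_peak = NA_real_,
                 fwhm_duration = NA_real_, fwhm_start = as.POSIXct(NA),
                 fwhm_end = as.POSIXct(NA), average_in_fwhm = NA_real_,
                 value_p90 = NA_real_, time_to_p90 = NA_real_,
                 n_bins = 0L, found = FALSE), class = "response_metrics")
}

# merge supra-half-max runs separated by < merge_gap sub-threshold minutes
#' @noRd
merge_blocks <- function(supra, merge_gap) {
  repeat {
    r <- rle(supra)
    len <- length(r$lengths)
    if (len < 3L) return(supra)
    # internal FALSE runs flanked by TRUE runs
    idx <- which(!r$values & seq_along(r$values) > 1L &
                   seq_along(r$values) < len & r$lengths < merge_gap)
    if (!length(idx)) return(supra)
    r$values[idx] <- TRUE
    supra <- inverse.rle(r)
  }
}

# [start, end] indices of the TRUE run containing position i
#' @noRd
block_of <- function(supra, i) {
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  j <- which(starts <= i & ends >= i)
  c(starts[j], ends[j])
}

#' @export
print.response_metrics <- function(x, ...) {
  if (!x$found) {
    cat("<response_metrics> ", x$event_type, ": no response found\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "<response_metrics> %s @ %s\n  peak %.4f at %+.0f min; FWHM %.0f min; mean-in-FWHM %.4f; p90 %.4f at %+.0f min\n",
    x$event_type, format(x$event_time, "%Y-%m-%d %H:%M", tz = "UTC"),
    x$peak_value, x$time_to_peak, x$fwhm_duration, x$average_in_fwhm,
    x$value_p90, x$time_to_p90))
  invisible(x)
}

#' @export
as.data.frame.response_metrics <- function(x, ...) {
  data.frame(event_type = x$event_type, event_time = x$event_time,
             peak_value = x$peak_value, time_to_peak = x$time_to_peak,
             fwhm_duration = x$fwhm_duration,
             average_in_fwhm = x$average_in_fwhm, value_p90 = x$value_p90,
             time_to_p90 = x$time_to_p90, found = x$found)
}

#' Responses to a list of events
#'
#' Smooths the minute series once and applies [find_response()] at each
#' event, with the event-type default search windows: lights-on +/- 3 h,
#' lights-off 0..720 min (the full dark period), cage-change 0..6 h.
#'
#' @param series a raw (unsmoothed) 1-min `activity_ts`.
#' @param events `POSIXct` vector of event instants.
#' @param event_type label; selects the default window.
#' @param search_window optional override (minutes relative to event).
#' @param smooth_window smoothing window in minutes.
#' @param ... passed to [find_response()].
#' @return `data.frame` with one row per event (see
#'   [as.data.frame.response_metrics()]).
#' @export
event_responses <- function(series, events, event_type = c("cage_change",
                                                           "lights_on",
                                                           "lights_off"),
                            search_window = NULL, smooth_window = 30, ...) {
  event_type <- match.arg(event_type)
  if (is.null(search_window)) {
    search_window <- switch(event_type,
                            lights_on = c(-180, 180),
                            lights_off = c(0, 720),
                            cage_change = c(0, 360))
  }
  sm <- smooth_series(series, smooth_window)
  out <- lapply(events, function(e) {
    as.data.frame(find_response(sm, e, search_window,
                                event_type = event_type, ...))
  })
  do.call(rbind, out)
}

#' Event-locked average response profile
#'
#' The averaged-response mode of response quantification (the counterpart of
#' the per-event [event_responses()]): the raw minute traces around each
#' event are aligned on the event instant and averaged across repeats (e.g.
#' the cage-changes of successive weeks), the averaged trace is smoothed, and
#' the FWHM metrics are computed once on it. Averaging across repeats
#' suppresses the minute-scale occupancy noise that can fragment the
#' supra-half-max block of a single low-amplitude response.
#'
#' @param series raw 1-min `activity_ts`.
#' @param events `POSIXct` event instants (all repeats of one event type).
#' @param search_window minutes relative to the event, e.g. `c(0, 360)`.
#' @param smooth_window smoothing window (minutes).
#' @param event_type label passed through to the metrics.
#' @param ... passed to [find_response()].
#' @return list of class `event_profile`: `trace` (averaged smoothed minute
#'   values over the window), `rel_min`, `n_events`, and `metrics` (a
#'   `response_metrics`).
#' @export
event_profile <- function(series, events, search_window = c(0, 360),
                          smooth_window = 30, event_type = "cage_change",
                          ...) {
  stopifnot(inherits(series, "activity_ts"))
  if (!isTRUE(all.equal(attr(series, "bin_width"), 60))) {
    stop("event_profile expects 1-min bins")
  }
  base <- as.numeric(series$bin_start[1])
  nmin <- nrow(series)
  lo <- search_window[1]
  hi <- search_window[2]
  wlen <- hi - lo
  rows <- (as.numeric(events) - base) / 60 + lo + 1
  ok <- rows >= 1 & (rows + wlen - 1) <= nmin & rows == round(rows)
  if (!any(ok)) stop("no event window fully inside the series")
  mat <- vapply(rows[ok], function(r) series$activity[r:(r + wlen - 1)],
                numeric(wlen))
  avg <- rowMeans(mat, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  sm <- moving_average(avg, smooth_window)
  e1 <- events[ok][1]
  wrap <- as_activity_ts(
    data.frame(bin_start = e1 + (lo + seq_len(wlen) - 1) * 60,
               date = utc_date(e1), tod_min = NA_real_, phase = NA_character_,
               week = NA_integer_, cycle_day = NA_integer_,
               events = NA_integer_, valid_slots = NA_integer_,
               activity = sm),
    attr(series, "cage_id"), 60)
  attr(wrap, "smoothed") <- smooth_window
  metrics <- find_response(wrap, e1, search_window, event_type = event_type,
                           ...)
  structure(list(trace = sm, rel_min = lo + seq_len(wlen) - 1,
                 n_events = sum(ok), metrics = metrics),
            class = "event_profile")
}

#' @export
print.event_profile <- function(x, ...) {
  cat("<event_profile> averaged over ", x$n_events, " event(s)\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Average lights-off response profile of a cage
#'
#' Extracts the 720 minute bins following each lights-off transition,
#' averages the minute trace across the selected dark periods, smooths it
#' (30-min moving average) and normalizes so the peak equals 1.0. Metrics are
#' computed on the averaged, smoothed, normalized trace over the full dark
#' period: time to peak, and the 90th-percentile value of the trace with its
#' first crossing time.
#'
#' @param series raw 1-min `activity_ts`.
#' @param schedule a [light_schedule()].
#' @param weeks optional vector of week indices to include (requires week
#'   labels on the series).
#' @param smooth_window smoothing window (minutes).
#' @param p90_mode see [find_response()].
#' @return Object of class `lights_off_profile`: `trace` (length 720,
#'   max exactly 1), `n_periods`, `time_to_peak` (min), `peak_raw` (activity
#'   units before normalization), `value_p90`, `time_to_p90`, and `fwhm`
#'   (a `response_metrics` for the dark-period response).
#' @export
lights_off_profile <- function(series, schedule, weeks = NULL,
                               smooth_window = 30,
                               p90_mode = "window_quantile") {
  stopifnot(inherits(series, "activity_ts"))
  bw <- attr(series, "bin_width")
  if (!isTRUE(all.equal(bw, 60))) stop("lights_off_profile expects 1-min bins")
  t0 <- series$bin_start[1]
  tn <- series$bin_start[nrow(series)]
  offs <- lights_off_times(schedule, t0, tn - 719 * 60)
  if (!is.null(weeks)) {
    wk <- series$week[match(as.numeric(offs), as.numeric(series$bin_start))]
    offs <- offs[!is.na(wk) & wk %in% weeks]
  }
  if (!length(offs)) stop("no complete dark period in the series")
  base <- as.numeric(series$bin_start[1])
  rows <- vapply(as.numeric(offs), function(o) (o - base) / 60 + 1, numeric(1))
  if (any(rows != round(rows))) stop("series not aligned to the minute grid")
  mat <- vapply(rows, function(r) series$activity[r:(r + 719)],
                numeric(720))                      # 720 x n_periods
  avg <- rowMeans(mat, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  sm <- moving_average(avg, smooth_window)
  pk <- max(sm, na.rm = TRUE)
  if (!is.finite(pk) || pk <= 0) {
    stop("zero-activity dark period: cannot normalize lights-off profile")
  }
  trace <- sm / pk
  ipk <- which.max(trace)
  p90 <- if (identical(p90_mode, "window_quantile")) {
    as.numeric(stats::quantile(trace, 0.9, na.rm = TRUE, names = FALSE))
  } else 0.9
  i90 <- which(!is.na(trace) & trace >= p90)[1]

  # FWHM metrics on an activity_ts wrapper of the averaged trace
  wrap <- as_activity_ts(
    data.frame(bin_start = offs[1] + (0:719) * 60,
               date = utc_date(offs[1]), tod_min = NA_real_,
               phase = "night", week = NA_integer_, cycle_day = NA_integer_,
               events = NA_integer_, valid_slots = NA_integer_,
               activity = sm),
    attr(series, "cage_id"), 60)
  attr(wrap, "smoothed") <- smooth_window
  fwhm <- find_response(wrap, offs[1], c(0, 720), event_type = "lights_off",
                        p90_mode = p90_mode)

  structure(list(trace = trace, n_periods = length(offs),
                 time_to_peak = ipk - 1, peak_raw = pk,
                 value_p90 = p90,
                 time_to_p90 = if (is.na(i90)) NA_real_ else i90 - 1,
                 fwhm = fwhm, cage_id = attr(series, "cage_id")),
            class = "lights_off_profile")
}

#' @export
print.lights_off_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "<lights_off_profile> cage %s: %d dark period(s)\n",
    "  time to peak %.0f min; p90 %.3f at %.0f min; peak %.4f activations\n"),
    x$cage_id, x$n_periods, x$time_to_peak, x$value_p90, x$time_to_p90,
    x$peak_raw))
  invisible(x)
}

#' @export
plot.lights_off_profile <- function(x, ...) {
  graphics::plot(0:719, x$trace, type = "l", xlab = "min after lights-off",
                 ylab = "activity (peak = 1)", ...)
  graphics::abline(v = x$time_to_peak, lty = 2)
  invisible(x)
}

#' Aggregate response metrics across repeats
#'
#' Grouped means, SDs, counts and quartiles of the FWHM response metrics —
#' the analysis-ready longitudinal export for comparisons across weeks,
#' cycle days, sites or sexes (the statistical tests themselves are external
#' to this package).
#'
#' @param metrics a `data.frame` of responses (e.g. from [event_responses()],
#'   possibly augmented with grouping columns), or a list of
#'   `response_metrics`.
#' @param keys character vector of grouping column names (may be empty for a
#'   single overall group).
#' @return `data.frame` of class `response_summary`, one row per observed
#'   group, with `<field>_mean`, `<field>_sd`, `<field>_q25`, `<field>_q75`
#'   for each metric field and the group size `n`.
#' @export
aggregate_responses <- function(metrics, keys = character(0)) {
  if (is.list(metrics) && !is.data.frame(metrics)) {
    metrics <- do.call(rbind, lapply(metrics, as.data.frame))
  }
  metrics <- metrics[isTRUE_vec(metrics$found), , drop = FALSE]
  fields <- c("peak_value", "time_to_peak", "fwhm_duration",
              "average_in_fwhm", "value_p90", "time_to_p90")
  fields <- intersect(fields, names(metrics))
  g <- if (length(keys)) {
    interaction(metrics[keys], drop = TRUE, lex.order = TRUE)
  } else {
    factor(rep("all", nrow(metrics)))
  }
  rows <- lapply(levels(g), function(lv) {
    m <- metrics[g == lv, , drop = FALSE]
    out <- if (length(keys)) unique(m[keys]) else data.frame(group = "all")
    rownames(out) <- NULL
    out$n <- nrow(m)
    for (f in fields) {
      x <- m[[f]]
      out[[paste0(f, "_mean")]] <- mean(x, na.rm = TRUE)
      out[[paste0(f, "_sd")]] <- if (nrow(m) > 1) sd(x, na.rm = TRUE) else 0
      out[[paste0(f, "_q25")]] <- as.numeric(quantile(x, 0.25, na.rm = TRUE))
      out[[paste0(f, "_q75")]] <- as.numeric(quantile(x, 0.75, na.rm = TRUE))
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("response_summary", "data.frame")
  out
}

#' @noRd
isTRUE_vec <- function(x) if (is.null(x)) TRUE else x %in% TRUE
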