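#' Detect activation events from the first-order difference
#'
#' The basic activity metric: for each electrode, the absolute value of the
#' difference between two successive 250 ms capacitance readings is compared
#' against a noise threshold; a pair whose difference exceeds the threshold is
#' an *activation event*. A pair is only formed where the two samples are at
#' most `max_pair_gap` apart (differencing never spans recording gaps) and
#' both readings are finite; invalid pairs are excluded from both the event
#' numerator and the slot denominator downstream.
#'
#' @param signal a [signal_table()].
#' @param threshold either a numeric threshold in capacitance units (length 1,
#'   applied to all electrodes, or length 12 per-electrode), or a list
#'   `list(policy = "mad", k = 4, quiescent_window = NULL)` in which case
#'   [estimate_noise_threshold()] is called.
#' @param max_pair_gap maximum spacing (seconds) between the two samples of a
#'   pair; default twice the sampling period.
#' @param schedule optional [light_schedule()], forwarded to the threshold
#'   estimator to locate the mid-day quiescent window.
#' @param assume_clean set `TRUE` when the caller guarantees a gap-free,
#'   all-finite signal (e.g. simulator output): skips the per-pair validity
#'   bookkeeping, so every pair is a valid slot.
#' @return Object of class `activation_series`: `cage_id`, `pair_timestamps`
#'   (instant of the later sample of each pair), `events` and `valid` logical
#'   matrices (pairs x 12), `threshold_used` (per electrode), `n_valid_pairs`.
#' @examples
#' t0 <- as.POSIXct("2023-01-05 00:00:00", tz = "UTC")
#' v <- matrix(1, 3, 12); v[3, 1] <- 1.3
#' acts <- detect_activations(signal_table(v, t0 + (0:2) * 0.25), threshold = 0.2)
#' acts$events[, 1]   # FALSE TRUE: |1.3 - 1.0| > 0.2
#' @export
detect_activations <- function(signal, threshold = list(policy = "mad", k = 4),
                               max_pair_gap = 2 * signal$sampling_period,
                               schedule = NULL, assume_clean = FALSE) {
  stopifnot(inherits(signal, "signal_table"))
  n <- nrow(signal$values)
  if (n < 2L) {
    warning("fewer than 2 samples: no pairs")
    return(activation_series(signal$cage_id,
                             signal$timestamps[integer(0)],
                             matrix(FALSE, 0, 12), matrix(FALSE, 0, 12),
                             rep(NA_real_, 12)))
  }
  if (is.list(threshold)) {
    theta <- estimate_noise_threshold(signal, k = threshold$k %||% 4,
                                      quiescent_window = threshold$quiescent_window,
                                      schedule = schedule,
                                      per_electrode = threshold$per_electrode %||% TRUE)
  } else {
    theta <- rep_len(as.numeric(threshold), 12L)
  }
  if (any(!is.finite(theta)) || any(theta < 0)) {
    stop("thresholds must be finite and non-negative")
  }
  d <- abs(signal$values[-1L, , drop = FALSE] -
             signal$values[-n, , drop = FALSE])
  if (assume_clean) {
    events <- d > rep(theta, each = n - 1L)
    return(activation_series(signal$cage_id, signal$timestamps[-1L], events,
                             NULL, theta))
  }
  gap_ok <- diff(as.numeric(signal$timestamps)) <= max_pair_gap + 1e-9
  fin <- is.finite(signal$values)
  valid <- fin[-1L, , drop = FALSE] & fin[-n, , drop = FALSE] & gap_ok
  events <- valid & sweep(d, 2L, theta, ">")
  events[!valid] <- FALSE
  if (!any(valid)) warning("all sample pairs invalid: empty activation series")
  activation_series(signal$cage_id, signal$timestamps[-1L], events, valid, theta)
}

# internal constructor (also used by tests to build exact event patterns);
# valid = NULL means "all pairs valid" (clean-signal fast path)
#' @noRd
activation_series <- function(cage_id, pair_timestamps, events, valid,
                              threshold_used) {
  colnames(events) <- ELECTRODE_COLS
  if (!is.null(valid)) colnames(valid) <- ELECTRODE_COLS
  structure(list(cage_id = cage_id, pair_timestamps = pair_timestamps,
                 events = events, valid = valid,
                 threshold_used = threshold_used,
                 n_valid_pairs = if (is.null(valid)) rep(nrow(events), 12L)
                                 else as.integer(colSums(valid))),
            class = "activation_series")
}

#' @export
print.activation_series <- function(x, ...) {
  cat("<activation_series> cage ", x$cage_id, ": ", nrow(x$events),
      " pairs x 12 electrodes; ", sum(x$events), " events on ",
      sum(x$n_valid_pairs), " valid slots\n", sep = "")
  invisible(x)
}

#' Estimate per-electrode noise thresholds
#'
#' The threshold separates capacitance variation due to electronic noise from
#' variation due to animal movement. It is set to `k` times a robust scale
#' (median absolute deviation, scaled by 1.4826 for Gaussian consistency) of
#' the signed first differences in a quiescent window. Daytime is rest for
#' nocturnal mice, so when a light schedule is supplied the default window is
#' mid-day (3 to 9 h after lights-on); otherwise all pairs are used.
#'
#' @param signal a [signal_table()].
#' @param k threshold multiplier (default 4).
#' @param quiescent_window optional `POSIXct` length-2 vector restricting the
#'   pairs used for estimation.
#' @param schedule optional [light_schedule()] used to pick the mid-day window.
#' @param per_electrode if `FALSE`, one pooled threshold is applied to every
#'   electrode (whether the system uses a global or per-electrode threshold is
#'   an open design point; per-electrode is the default).
#' @return numeric vector of 12 thresholds (capacitance units).
#' @export
estimate_noise_threshold <- function(signal, k = 4, quiescent_window = NULL,
                                     schedule = NULL, per_electrode = TRUE) {
  stopifnot(inherits(signal, "signal_table"))
  n <- nrow(signal$values)
  if (n < 2L) stop("need at least 2 samples to estimate noise")
  d <- signal$values[-1L, , drop = FALSE] - signal$values[-n, , drop = FALSE]
  gap_ok <- diff(as.numeric(signal$timestamps)) <= 2 * signal$sampling_period + 1e-9
  fin <- is.finite(signal$values)
  valid <- fin[-1L, , drop = FALSE] & fin[-n, , drop = FALSE] & gap_ok
  tlater <- signal$timestamps[-1L]

  keep <- rep(TRUE, length(tlater))
  if (!is.null(quiescent_window)) {
    keep <- tlater >= quiescent_window[1] & tlater <= quiescent_window[2]
  } else if (!is.null(schedule)) {
    m <- minute_of_day(tlater)
    lo <- (schedule$on_min + 180) %% 1440
    hi <- (schedule$on_min + 540) %% 1440
    keep <- if (lo < hi) m >= lo & m < hi else m >= lo | m < hi
    if (sum(keep) < 100L) keep <- rep(TRUE, length(tlater))  # short recordings
  }

  if (per_electrode) {
    theta <- vapply(1:12, function(e) {
      x <- d[keep & valid[, e], e]
      if (length(x) < 100L) {
        stop("insufficient valid pairs (", length(x),
             ") to estimate noise for electrode ", ELECTRODE_COLS[e])
      }
      k * stats::mad(x)
    }, numeric(1))
  } else {
    x <- d[keep & valid]
    if (length(x) < 100L) stop("insufficient valid pairs (", length(x),
                               ") to estimate a pooled noise scale")
    theta <- rep(k * stats::mad(x), 12L)
  }
  names(theta) <- ELECTRODE_COLS
  theta
}
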