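#' Day x time-of-day heat-map matrix
#'
#' Reshapes a minute activity series into the matrix behind the classic
#' activity heat map: one row per calendar day, one column per time-of-day
#' bin. Values are activity fractions; missing bins are `NA`.
#'
#' @param series a 1-min `activity_ts`.
#' @param days optional vector of `Date`s to include.
#' @param tod_bin column width in minutes (default 1; must divide 1440).
#' @return numeric matrix of class `activity_heatmap` (days x bins) with
#'   day dates as row names.
#' @export
heatmap_matrix <- function(series, days = NULL, tod_bin = 1) {
  stopifnot(inherits(series, "activity_ts"))
  if (1440 %% tod_bin != 0) stop("tod_bin must divide 1440")
  if (!isTRUE(all.equal(attr(series, "bin_width"), 60))) {
    stop("heatmap_matrix expects 1-min bins")
  }
  if (is.null(days)) days <- sort(unique(series$date))
  ncol <- 1440 %/% tod_bin
  mat <- matrix(NA_real_, length(days), ncol,
                dimnames = list(as.character(days), NULL))
  col <- floor(series$tod_min / tod_bin) + 1L
  row <- match(series$date, days)
  keep <- !is.na(row)
  if (tod_bin == 1) {
    mat[cbind(row[keep], col[keep])] <- series$activity[keep]
  } else {
    agg <- tapply(series$activity[keep],
                  list(row[keep], col[keep]), mean, na.rm = TRUE)
    mat[as.numeric(rownames(agg)), as.numeric(colnames(agg))] <- agg
  }
  class(mat) <- c("activity_heatmap", class(mat))
  attr(mat, "tod_bin") <- tod_bin
  mat
}

#' @export
plot.activity_heatmap <- function(x, ...) {
  graphics::image(t(unclass(x))[, rev(seq_len(nrow(x))), drop = FALSE],
                  xlab = "time of day", ylab = "day", axes = FALSE, ...)
  invisible(x)
}

#' Actigram: hourly day and night traces
#'
#' Hourly means (and SDs) of per-minute activity, with the day trace anchored
#' at lights-on and the night trace anchored at lights-off (a 12 h phase
#' shift), so the two 12-bin traces can be superimposed as in the standard
#' actigram display.
#'
#' @param series a 1-min `activity_ts` with phase labels.
#' @param schedule the [light_schedule()].
#' @param weeks optional week selection (requires week labels).
#' @return `data.frame` of class `actigram`: `hour` (0-11 from the phase
#'   transition), `day_mean`, `day_sd`, `night_mean`, `night_sd`, `n_days`.
#' @export
actigram <- function(series, schedule, weeks = NULL) {
  stopifnot(inherits(series, "activity_ts"))
  if (!is.null(weeks)) series <- series[series$week %in% weeks, ]
  if (!nrow(series)) stop("no data in selection")
  m <- series$tod_min
  since_on <- (m - schedule$on_min) %% 1440
  since_off <- (m - schedule$off_min) %% 1440
  is_day <- since_on < 720
  hr_day <- floor(since_on / 60)
  hr_night <- floor(since_off / 60)
  stat <- function(v) c(mean = mean(v, na.rm = TRUE),
                        sd = if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0)
  out <- data.frame(hour = 0:11)
  dm <- sapply(0:11, function(h) stat(series$activity[is_day & hr_day == h]))
  nm <- sapply(0:11, function(h) stat(series$activity[!is_day & hr_night == h]))
  out$day_mean <- dm["mean", ]
  out$day_sd <- dm["sd", ]
  out$night_mean <- nm["mean", ]
  out$night_sd <- nm["sd", ]
  out$n_days <- length(unique(series$date))
  class(out) <- c("actigram", "data.frame")
  out
}

#' @export
plot.actigram <- function(x, ...) {
  rng <- range(c(x$day_mean, x$night_mean), na.rm = TRUE)
  graphics::plot(x$hour, x$night_mean, type = "l", col = "red", ylim = rng,
                 xlab = "h after phase transition", ylab = "activity", ...)
  graphics::lines(x$hour, x$day_mean, col = "blue")
  graphics::legend("topright", legend = c("night", "day"),
                   col = c("red", "blue"), lty = 1, bty = "n")
  invisible(x)
}

#' Longitudinal table for rank-based repeated-measures analysis
#'
#' One row per (cage, week, cycle day, phase) with the slot-weighted mean
#' activity, the valid-slot weight, and activity normalized per cage-change
#' cycle — the export consumed by external nonparametric longitudinal tests
#' (cages as subjects; weeks and days post cage-change as within-subject
#' factors). Rows cover only observed combinations; an incomplete trailing
#' cycle is included and flagged in the `complete_cycle` column.
#'
#' @param series a labelled `activity_ts` (see [bin_activity()]).
#' @param config optional [study_config()] contributing `site` and `sex`
#'   columns for the cage.
#' @return `data.frame` of class `longitudinal_table`.
#' @export
build_longitudinal_table <- function(series, config = NULL) {
  stopifnot(inherits(series, "activity_ts"))
  if (all(is.na(series$week))) stop("series has no cycle labels; ",
                                    "bin with a calendar first")
  norm <- normalize_activity(series, "cycle")
  s <- series[!is.na(series$week) & !is.na(series$phase), ]
  nv <- norm$activity[!is.na(series$week) & !is.na(series$phase)]
  key <- interaction(s$week, s$cycle_day, s$phase, drop = TRUE)
  rows <- lapply(levels(key), function(lv) {
    i <- which(key == lv)
    slots <- sum(s$valid_slots[i])
    data.frame(week = s$week[i][1], cycle_day = s$cycle_day[i][1],
               phase = s$phase[i][1],
               activity = if (slots > 0) sum(s$events[i]) / slots else NA_real_,
               valid_slots = slots,
               normalized = mean(nv[i], na.rm = TRUE),
               n_bins = length(i))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$week, out$cycle_day, out$phase), ]
  rownames(out) <- NULL
  out$cage_id <- attr(series, "cage_id")
  max_day <- max(out$cycle_day)
  complete_weeks <- tapply(out$cycle_day, out$week,
                           function(d) length(unique(d)))
  full <- as.numeric(names(complete_weeks))[complete_weeks ==
                                              max(complete_weeks)]
  out$complete_cycle <- out$week %in% full
  if (!is.null(config)) {
    meta <- config$cages[match(out$cage_id, config$cages$cage_id), ,
                         drop = FALSE]
    out$site <- meta$site
    out$sex <- meta$sex
  }
  class(out) <- c("longitudinal_table", "data.frame")
  out
}

#' Permutation check of cycle-day exchangeability
#'
#' Negative-control diagnostic: with interventions disabled, the weekday of
#' the cage-change cycle should carry no information, i.e. the per-(week,
#' cycle-day) activity values are exchangeable across cycle days. The
#' statistic is the between-cycle-day sum of squares of the daytime (or
#' night) activity values; its permutation distribution is obtained by
#' shuffling the cycle-day labels across all (week, day) cells.
#'
#' @param lt a [build_longitudinal_table()] output.
#' @param phase `"day"` or `"night"` values to test.
#' @param value `"activity"` or `"normalized"`.
#' @param n_perm number of permutations (default 199).
#' @return list with `p_value`, `statistic`, `n_cells`.
#' @export
cycle_day_exchangeability <- function(lt, phase = "day", value = "activity",
                                      n_perm = 199) {
  x <- lt[lt$phase == phase & lt$complete_cycle, ]
  v <- x[[value]]
  d <- x$cycle_day
  ok <- !is.na(v)
  v <- v[ok]
  d <- d[ok]
  if (length(unique(d)) < 2L || length(v) < 4L) {
    stop("need at least two cycle days with data")
  }
  ss_between <- function(vals, lab) {
    gm <- mean(vals)
    sum(tapply(vals, lab, function(z) length(z) * (mean(z) - gm)^2))
  }
  obs <- ss_between(v, d)
  perm <- replicate(n_perm, ss_between(v, sample(d)))
  list(p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
       statistic = obs, n_cells = length(v))
}
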