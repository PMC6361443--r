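ELECTRODE_COLS <- sprintf("e%02d", 1:12)

#' Raw capacitance signal table for one cage
#'
#' A `signal_table` holds the raw 4 Hz capacitance readings of the 12
#' under-floor electrodes of one cage: a strictly increasing timestamp vector
#' and a numeric matrix with one column per electrode (index 1..12, front row
#' first). Capacitance is in dimensionless sensor units; no physical
#' calibration is attempted. Rows containing non-finite readings are flagged
#' (kept, never silently dropped); the downstream pair-differencing treats
#' them as invalid.
#'
#' @param values numeric matrix with 12 columns (electrodes 1..12) or
#'   something coercible to one.
#' @param timestamps `POSIXct` vector (UTC), strictly increasing, one per row
#'   of `values`. Nominal spacing is `sampling_period`.
#' @param cage_id opaque cage identifier.
#' @param sampling_period nominal sampling period in seconds (default 0.25).
#' @return An object of class `signal_table` with fields `cage_id`,
#'   `timestamps`, `values`, `sampling_period` and attribute-like field
#'   `flagged_rows` (row indices with non-finite readings).
#' @examples
#' t0 <- as.POSIXct("2023-01-05 00:00:00", tz = "UTC")
#' sig <- signal_table(matrix(rnorm(36), 3, 12), t0 + (0:2) * 0.25, "C1")
#' sig
#' @export
signal_table <- function(values, timestamps, cage_id = "cage",
                         sampling_period = 0.25) {
  values <- as.matrix(values)
  if (ncol(values) != 12L) {
    stop("signal_table requires exactly 12 electrode columns, got ", ncol(values))
  }
  storage.mode(values) <- "double"
  colnames(values) <- ELECTRODE_COLS
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  if (length(timestamps) != nrow(values)) {
    stop("length(timestamps) must equal nrow(values)")
  }
  if (nrow(values) > 1L) {
    dt <- diff(as.numeric(timestamps))
    if (any(dt <= 0)) {
      stop("timestamps must be strictly increasing; first offending row: ",
           which(dt <= 0)[1] + 1L)
    }
  }
  flagged <- which(rowSums(!is.finite(values)) > 0L)
  structure(
    list(cage_id = as.character(cage_id)[1], timestamps = timestamps,
         values = values, sampling_period = sampling_period,
         flagged_rows = flagged),
    class = "signal_table")
}

#' @export
print.signal_table <- function(x, ...) {
  cat("<signal_table> cage ", x$cage_id, ": ", nrow(x$values),
      " samples x 12 electrodes @ ", x$sampling_period * 1000, " ms\n", sep = "")
  if (nrow(x$values)) {
    cat("  span: ", format_iso_ms(x$timestamps[1]), " .. ",
        format_iso_ms(x$timestamps[length(x$timestamps)]), "\n", sep = "")
  }
  if (length(x$flagged_rows)) {
    cat("  flagged rows (non-finite readings): ", length(x$flagged_rows), "\n",
        sep = "")
  }
  invisible(x)
}

#' Read a raw capacitance signal CSV
#'
#' The on-disk dialect is a plain CSV with header
#' `cage_id,timestamp,e01,...,e12`, one row per 250 ms sample, timestamps in
#' ISO-8601 with milliseconds and a UTC offset. Electrode columns may appear
#' in any order; they are normalized to index order. Rows whose timestamp
#' does not parse are rejected and counted (a message reports the count);
#' a missing electrode column or non-monotonic timestamps are fatal.
#'
#' @param path path to the CSV file.
#' @return A validated [signal_table()] with attribute `n_rejected` giving the
#'   number of rows dropped for unparseable timestamps.
#' @seealso [write_signal()]
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "timestamp"),
                          showProgress = FALSE)
  need <- c("cage_id", "timestamp", ELECTRODE_COLS)
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("signal file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ts <- parse_iso_ms(dt[["timestamp"]])
  n_rejected <- sum(is.na(ts))
  if (n_rejected > 0L) {
    message("read_signal: rejected ", n_rejected,
            " row(s) with unparseable timestamps")
    keep <- !is.na(ts)
    dt <- dt[keep]
    ts <- ts[keep]
  }
  if (length(ts) > 1L) {
    bad <- which(diff(as.numeric(ts)) <= 0)
    if (length(bad)) {
      stop("non-monotonic timestamps in ", path, " at data row ", bad[1] + 1L)
    }
  }
  cage <- if (nrow(dt)) as.character(dt[["cage_id"]][1]) else "cage"
  vals <- as.matrix(dt[, ELECTRODE_COLS, with = FALSE])
  if (!nrow(vals)) vals <- matrix(numeric(0), 0, 12)
  out <- signal_table(vals, ts, cage_id = cage)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a raw capacitance signal CSV
#'
#' Emits the dialect read by [read_signal()]; `read_signal(write_signal(x))`
#' reproduces `x` (values exactly, timestamps to the millisecond). Writing the
#' same table twice yields byte-identical files.
#'
#' @param table a [signal_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_signal <- function(table, path) {
  stopifnot(inherits(table, "signal_table"))
  n <- nrow(table$values)
  dt <- data.table::as.data.table(table$values)
  data.table::set(dt, j = "cage_id", value = rep(table$cage_id, n))
  data.table::set(dt, j = "timestamp",
                  value = if (n) format_iso_ms(table$timestamps) else character(0))
  data.table::setcolorder(dt, c("cage_id", "timestamp", ELECTRODE_COLS))
  ok <- tryCatch({
    data.table::fwrite(dt, path, showProgress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write signal file ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
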