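# Internal time helpers. All instants in the package are POSIXct, UTC.
# On disk, timestamps are ISO-8601 with milliseconds and an explicit UTC
# offset ("2023-01-05T00:00:00.250+00:00"); the native sampling period is
# 250 ms so millisecond precision is exact.

.TS_REGEX <- "^(\\d{4}-\\d{2}-\\d{2})T(\\d{2}:\\d{2}:\\d{2})(\\.\\d+)?(\\+00:00|\\+0000|Z)$"

#' @noRd
parse_iso_ms <- function(x) {
  m <- regmatches(x, regexec(.TS_REGEX, x))
  bad <- vapply(m, length, 1L) == 0L
  date <- vapply(m, function(p) if (length(p)) p[2] else NA_character_, "")
  time <- vapply(m, function(p) if (length(p)) p[3] else NA_character_, "")
  frac <- vapply(m, function(p) if (length(p)) p[4] else "", "")
  base <- as.POSIXct(paste(date, time), format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  fsec <- ifelse(frac == "" | is.na(frac), 0, as.numeric(paste0("0", frac)))
  out <- base + fsec
  out[bad] <- NA
  out
}

#' @noRd
format_iso_ms <- function(t) {
  ms <- round(as.numeric(t) * 1000)
  whole <- .POSIXct(ms %/% 1000, tz = "UTC")
  paste0(format(whole, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
         sprintf(".%03d", as.integer(ms %% 1000)), "+00:00")
}

# "HH:MM" clock string -> minutes after midnight
#' @noRd
clock_to_minutes <- function(x) {
  if (!is.character(x) || !all(grepl("^\\d{1,2}:\\d{2}$", x))) {
    stop("clock times must be 'HH:MM' strings, got: ", paste(x, collapse = ", "))
  }
  h <- as.integer(sub(":.*", "", x))
  m <- as.integer(sub(".*:", "", x))
  if (any(h > 23) || any(m > 59)) stop("clock time out of range: ", x)
  h * 60 + m
}

# minutes-of-day (UTC) of a POSIXct vector
#' @noRd
minute_of_day <- function(t) {
  (as.numeric(t) %% 86400) / 60
}

#' @noRd
utc_date <- function(t) {
  as.Date(as.POSIXlt(t, tz = "UTC"))
}
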