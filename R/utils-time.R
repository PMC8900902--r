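# Time conventions: all timestamps are naive local time stored as POSIXct
# with tz = "UTC" (the study is single-timezone; no DST arithmetic wanted).
# Clock-of-day values are hms. Minutes are half-open [m, m + 60 s).

.tz <- "UTC"

#' Coerce a clock-of-day value
#'
#' Accepts `hms`, `"HH:MM"` / `"HH:MM:SS"` strings, or numeric seconds since
#' midnight and returns an [hms::hms] value. `24:00:00` is allowed as an
#' exclusive end-of-day bound.
#'
#' @param x clock time in any accepted form.
#' @return an `hms` scalar or vector.
#' @keywords internal
as_clock <- function(x) {
  if (hms::is_hms(x)) {
    return(x)
  }
  if (is.numeric(x)) {
    return(hms::as_hms(x))
  }
  if (is.character(x)) {
    parts <- strsplit(x, ":", fixed = TRUE)
    secs <- vapply(parts, function(p) {
      p <- suppressWarnings(as.numeric(p))
      if (any(is.na(p)) || length(p) < 2 || length(p) > 3) {
        stop("unparseable clock time", call. = FALSE)
      }
      sum(p * c(3600, 60, 1)[seq_along(p)])
    }, numeric(1))
    if (any(secs < 0 | secs > 86400)) {
      stop("clock time outside 00:00:00-24:00:00", call. = FALSE)
    }
    return(hms::as_hms(secs))
  }
  stop("cannot interpret clock time of class ", paste(class(x), collapse = "/"),
    call. = FALSE
  )
}

#' Seconds since local midnight of a timestamp
#' @param ts POSIXct vector.
#' @return numeric seconds in [0, 86400).
#' @keywords internal
clock_seconds <- function(ts) {
  as.numeric(ts) - as.numeric(lubridate::floor_date(ts, "day"))
}

#' Floor timestamps to the containing minute
#' @param ts POSIXct vector.
#' @return POSIXct vector aligned to :00 seconds.
#' @keywords internal
floor_minute <- function(ts) {
  lubridate::floor_date(ts, "minute")
}

# POSIXct constructor from a calendar day index and seconds-of-day.
# day_index is 1-based within the deployment.
day_time <- function(start_date, day_index, secs) {
  as.POSIXct(as.numeric(as.POSIXct(start_date, tz = .tz)) +
    (day_index - 1) * 86400 + secs, tz = .tz, origin = "1970-01-01")
}

empty_timestamp <- function() {
  as.POSIXct(character(), tz = .tz)
}
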