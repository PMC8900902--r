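# Eating-event detection from hand-to-mouth gesture timestamps.

#' Cluster gestures into detected eating events
#'
#' Implements the in-field detection rule: a cluster of at least
#' `min_gestures` hand-to-mouth gestures within a one-minute time frame is
#' characterized as an eating event. The "within a minute" relation is read
#' as single-linkage in time — two gestures belong to the same cluster iff
#' they are connected by a chain of gestures with consecutive gaps of at
#' most `window_seconds` — rather than a fixed calendar-minute bin, which
#' would split bouts straddling a minute boundary. Event start/end are the
#' first/last gesture timestamps of the cluster.
#'
#' @param gestures tibble with `participant_id` and `timestamp` (POSIXct,
#'   second resolution) for a single participant; unsorted input is sorted
#'   internally, and duplicate timestamps are allowed.
#' @param window_seconds maximum within-cluster gap, seconds (default 60).
#' @param min_gestures minimum cluster size to qualify as an event
#'   (default 2).
#' @return tibble `event_id`, `participant_id`, `start_ts`, `end_ts`,
#'   `gesture_count`, sorted by `start_ts`; events are maximal, so no two
#'   are within `window_seconds` of each other.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   participant_id = "p1",
#'   timestamp = as.POSIXct("2024-03-04 10:00:00", tz = "UTC") + c(0, 45)
#' )
#' detect_eating_events(g)
detect_eating_events <- function(gestures, window_seconds = 60,
                                 min_gestures = 2) {
  stopifnot(window_seconds > 0, min_gestures >= 1)
  empty <- tibble::tibble(
    event_id = character(), participant_id = character(),
    start_ts = empty_timestamp(), end_ts = empty_timestamp(),
    gesture_count = integer()
  )
  if (nrow(gestures) == 0) {
    return(empty)
  }
  pid <- unique(gestures$participant_id)
  if (length(pid) != 1) {
    stop("detect_eating_events() expects gestures of a single participant; got ",
      length(pid), " ids",
      call. = FALSE
    )
  }
  ts <- sort(as.numeric(gestures$timestamp))
  gaps <- diff(ts)
  cluster <- cumsum(c(0, gaps > window_seconds))
  sizes <- tabulate(cluster + 1)
  keep <- which(sizes >= min_gestures) - 1
  if (length(keep) == 0) {
    return(empty)
  }
  rows <- lapply(seq_along(keep), function(k) {
    idx <- cluster == keep[k]
    tibble::tibble(
      start_ts = as.POSIXct(min(ts[idx]), tz = .tz, origin = "1970-01-01"),
      end_ts = as.POSIXct(max(ts[idx]), tz = .tz, origin = "1970-01-01"),
      gesture_count = sum(idx)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$start_ts)
  tibble::tibble(
    event_id = sprintf("%s-E%04d", pid, seq_len(nrow(out))),
    participant_id = pid,
    out
  )
}

#' Discard detected events without beacon coverage
#'
#' Events are measured only at home; a detection is retained iff beacon
#' data are available for at least one minute overlapping its closed
#' `[start_ts, end_ts]` span. Minutes are half-open `[m, m + 60 s)`;
#' minutes with no record are treated as beacon-unavailable.
#'
#' @param events detected-event tibble (possibly several participants).
#' @param minutes sensor-minute tibble with `beacon_available`.
#' @return the retained events, order preserved.
#' @export
filter_at_home_events <- function(events, minutes) {
  if (nrow(events) == 0) {
    return(events)
  }
  beacon <- minutes[minutes$beacon_available, c("participant_id", "minute_start")]
  keep <- vapply(seq_len(nrow(events)), function(i) {
    m <- beacon$minute_start[beacon$participant_id == events$participant_id[i]]
    if (length(m) == 0) {
      return(FALSE)
    }
    m <- as.numeric(m)
    any(m < as.numeric(events$end_ts[i]) + 1 &
      m + 60 > as.numeric(events$start_ts[i]))
  }, logical(1))
  events[keep, ]
}
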