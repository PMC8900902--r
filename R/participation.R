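# The participation algorithm: fuse answered EMAs, accelerometer movement,
# and beacon availability into per-participant valid participation
# intervals, then keep only prompts received during participation.

#' Participation intervals anchored on answered prompts
#'
#' A participant who answered a prompt at time `t` is deemed participating
#' for the half-open interval `[t - radius, t + radius)` (default a
#' 30-minute window, t-15 to t+15 minutes). The anchor time is the
#' prompt's `received_ts` (a separate answer timestamp is not modelled).
#' Overlapping intervals are merged.
#'
#' @param prompts a prompt tibble; only rows with
#'   `answer_state != "not_answered"` anchor intervals.
#' @param radius_minutes half-width of the anchored interval, minutes.
#' @return a normalized participation-interval tibble.
#' @export
ema_anchor_intervals <- function(prompts, radius_minutes = 15) {
  stopifnot(radius_minutes >= 1)
  ans <- prompts[!is.na(prompts$answer_state) &
    prompts$answer_state != "not_answered", ]
  if (nrow(ans) == 0) {
    return(participation_intervals())
  }
  if (any(is.na(ans$received_ts))) {
    stop("answered prompts must carry received_ts", call. = FALSE)
  }
  normalize_intervals(participation_intervals(
    participant_id = ans$participant_id,
    start_ts = ans$received_ts - radius_minutes * 60,
    end_ts = ans$received_ts + radius_minutes * 60
  ))
}

#' Classify one minute as participating
#'
#' The sensor-side decision tree: a minute counts as participating iff the
#' accelerometer data are available *and* indicate movement *and* beacon
#' data are available. Vectorized over rows.
#'
#' @param minutes sensor-minute tibble with logical `accel_available`,
#'   `movement`, `beacon_available`.
#' @return logical vector, one element per row.
#' @export
classify_minute <- function(minutes) {
  minutes$accel_available & minutes$movement & minutes$beacon_available
}

#' Sensor-derived participation intervals
#'
#' Maximal runs of contiguous participating minutes (per
#' [classify_minute()]) are merged into half-open intervals
#' `[first_minute, last_minute + 60 s)`.
#'
#' @param minutes sensor-minute tibble; rows may be unsorted. Duplicate
#'   (participant, minute) records are rejected.
#' @return a normalized participation-interval tibble.
#' @export
sensor_intervals <- function(minutes) {
  if (nrow(minutes) == 0) {
    return(participation_intervals())
  }
  if (anyDuplicated(minutes[, c("participant_id", "minute_start")]) > 0) {
    stop("duplicate (participant, minute) sensor records", call. = FALSE)
  }
  part <- minutes[classify_minute(minutes), ]
  if (nrow(part) == 0) {
    return(participation_intervals())
  }
  normalize_intervals(participation_intervals(
    participant_id = part$participant_id,
    start_ts = part$minute_start,
    end_ts = part$minute_start + 60
  ))
}

#' Keep prompts received during participation
#'
#' Retains prompts that were received and whose `received_ts` lies inside
#' some participation interval of the same participant (half-open
#' membership). Non-received prompts are dropped regardless of intervals.
#'
#' @param prompts a prompt tibble with delivery resolved.
#' @param intervals a participation-interval tibble.
#' @return the retained prompts, order preserved.
#' @export
filter_prompts <- function(prompts, intervals) {
  if (nrow(prompts) == 0) {
    return(prompts)
  }
  intervals <- normalize_intervals(intervals)
  keep <- vapply(seq_len(nrow(prompts)), function(i) {
    if (!isTRUE(prompts$received[i])) {
      return(FALSE)
    }
    iv <- intervals[intervals$participant_id == prompts$participant_id[i], ]
    any(in_intervals(prompts$received_ts[i], iv$start_ts, iv$end_ts))
  }, logical(1))
  prompts[keep, ]
}

#' Run the full participation algorithm
#'
#' Convenience wrapper: EMA-anchored intervals from answered prompts,
#' sensor intervals from classified minutes, their union, and the filtered
#' prompt set.
#'
#' @param prompts a prompt tibble with delivery and answer states resolved.
#' @param minutes a sensor-minute tibble.
#' @param radius_minutes anchor half-width, minutes.
#' @return list with `ema_intervals`, `sensor_intervals`, `intervals`
#'   (the union), and `retained_prompts`.
#' @export
participation_algorithm <- function(prompts, minutes, radius_minutes = 15) {
  ema_iv <- ema_anchor_intervals(prompts, radius_minutes)
  sens_iv <- sensor_intervals(minutes)
  iv <- union_participation(ema_iv, sens_iv)
  list(
    ema_intervals = ema_iv,
    sensor_intervals = sens_iv,
    intervals = iv,
    retained_prompts = filter_prompts(prompts, iv)
  )
}
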