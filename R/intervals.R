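# Participation intervals are half-open [start_ts, end_ts), one row per
# interval, per participant. After normalization intervals are sorted,
# pairwise disjoint and non-adjacent (touching intervals are merged).

#' Construct a participation-interval tibble
#'
#' @param participant_id character vector.
#' @param start_ts,end_ts POSIXct bounds; each interval is half-open
#'   `[start_ts, end_ts)` and must satisfy `start_ts < end_ts`.
#' @return a tibble with columns `participant_id`, `start_ts`, `end_ts`.
#' @export
participation_intervals <- function(participant_id = character(),
                                    start_ts = empty_timestamp(),
                                    end_ts = empty_timestamp()) {
  out <- tibble::tibble(
    participant_id = as.character(participant_id),
    start_ts = start_ts,
    end_ts = end_ts
  )
  if (any(out$start_ts >= out$end_ts)) {
    stop("interval start_ts must precede end_ts", call. = FALSE)
  }
  out
}

# Merge sorted numeric half-open intervals; touching intervals merge.
merge_bounds <- function(start, end) {
  ord <- order(start, end)
  start <- start[ord]
  end <- end[ord]
  if (length(start) == 0) {
    return(list(start = start, end = end))
  }
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  list(start = c(out_s, ms), end = c(out_e, me))
}

#' Normalize participation intervals
#'
#' Sorts intervals and merges any that overlap or touch, per participant,
#' so the result is disjoint and non-adjacent.
#'
#' @param intervals a participation-interval tibble.
#' @return a normalized participation-interval tibble.
#' @export
normalize_intervals <- function(intervals) {
  if (nrow(intervals) == 0) {
    return(participation_intervals())
  }
  intervals |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::reframe({
      m <- merge_bounds(as.numeric(.data$start_ts), as.numeric(.data$end_ts))
      tibble::tibble(
        start_ts = as.POSIXct(m$start, tz = .tz, origin = "1970-01-01"),
        end_ts = as.POSIXct(m$end, tz = .tz, origin = "1970-01-01")
      )
    }) |>
    dplyr::arrange(.data$participant_id, .data$start_ts)
}

#' Union of participation interval sets
#'
#' Set-theoretic union of any number of interval tibbles, normalized to
#' disjoint sorted intervals per participant. Used to combine EMA-anchored
#' intervals (which dominate wherever present) with sensor-derived ones:
#' the union makes the precedence immaterial, since time covered by either
#' source is valid participation time.
#'
#' @param ... participation-interval tibbles.
#' @return a normalized participation-interval tibble.
#' @export
union_participation <- function(...) {
  normalize_intervals(dplyr::bind_rows(...))
}

# Membership of timestamps in a participant's normalized intervals,
# half-open convention.
in_intervals <- function(ts, start, end) {
  if (length(start) == 0) {
    return(rep(FALSE, length(ts)))
  }
  t <- as.numeric(ts)
  s <- as.numeric(start)
  e <- as.numeric(end)
  vapply(t, function(x) any(x >= s & x < e), logical(1))
}

#' Total participation time
#'
#' @param intervals a participation-interval tibble.
#' @return total covered time in seconds, summed over participants after
#'   normalization (so overlapping inputs are not double counted).
#' @export
participation_seconds <- function(intervals) {
  norm <- normalize_intervals(intervals)
  sum(as.numeric(norm$end_ts) - as.numeric(norm$start_ts))
}
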