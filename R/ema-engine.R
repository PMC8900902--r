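# EMA protocol engine: prompt scheduling, delivery, and answer-state
# bookkeeping. A prompt tibble has one row per prompt with columns
# prompt_id, participant_id, prompt_type, linked_event_id, sent_ts,
# received, received_ts, answer_state, first_question_eating, responses
# (list-column of named item responses).

new_prompts <- function(prompt_id = character(),
                        participant_id = character(),
                        prompt_type = character(),
                        linked_event_id = NA_character_,
                        sent_ts = empty_timestamp()) {
  tibble::tibble(
    prompt_id = prompt_id,
    participant_id = participant_id,
    prompt_type = prompt_type,
    linked_event_id = linked_event_id,
    sent_ts = sent_ts,
    received = NA,
    received_ts = as.POSIXct(rep(NA_real_, length(prompt_id)),
      tz = .tz, origin = "1970-01-01"
    ),
    answer_state = NA_character_,
    first_question_eating = NA_character_,
    responses = vector("list", length(prompt_id))
  )
}

#' Schedule hourly time-triggered prompts
#'
#' One prompt per clock-hour mark inside the participant's personalized
#' window, each deployment day. By convention both window ends are
#' inclusive: a prompt fires at hour mark `t` whenever
#' `window_start <= t <= window_end` (a 06:30-23:00 window yields prompts
#' 07:00 through 23:00). Set `inclusive_end = FALSE` to exclude a prompt
#' exactly at `window_end`. A window shorter than one hour may contain no
#' hour mark and then yields no prompts.
#'
#' @param profile one roster row with `window_start`, `window_end`.
#' @param deployment_days number of consecutive days to schedule.
#' @param start_date first deployment day.
#' @param inclusive_end logical; include a prompt exactly at `window_end`.
#' @return a prompt tibble with `prompt_type = "time_triggered"` and
#'   delivery state unresolved.
#' @export
schedule_time_triggered <- function(profile, deployment_days,
                                    start_date = "2024-03-04",
                                    inclusive_end = TRUE) {
  stopifnot(nrow(profile) == 1, deployment_days >= 1)
  w0 <- as.numeric(as_clock(profile$window_start))
  w1 <- as.numeric(as_clock(profile$window_end))
  if (w0 >= w1) stop("window_start must precede window_end", call. = FALSE)
  first_mark <- ceiling(w0 / 3600) * 3600
  last_mark <- if (inclusive_end) {
    floor(w1 / 3600) * 3600
  } else {
    floor((w1 - 1) / 3600) * 3600
  }
  if (first_mark > last_mark) {
    return(new_prompts())
  }
  marks <- seq(first_mark, last_mark, by = 3600)
  sent <- unlist(lapply(seq_len(deployment_days), function(day) {
    as.numeric(day_time(start_date, day, marks))
  }))
  new_prompts(
    prompt_id = sprintf("%s-T%05d", profile$participant_id, seq_along(sent)),
    participant_id = profile$participant_id,
    prompt_type = "time_triggered",
    sent_ts = as.POSIXct(sent, tz = .tz, origin = "1970-01-01")
  )
}

#' Trigger event-contingent prompts for detected eating events
#'
#' Each detected eating event produces one confirmation prompt sent
#' `delay_seconds` after the event ends. Prompts whose send time falls
#' outside the participant's personalized window (by clock time) are
#' suppressed: the protocol never contacts participants outside their
#' window.
#'
#' @param events detected-event tibble for one participant.
#' @param profile the participant's roster row.
#' @param delay_seconds non-negative delay from event end to prompt send.
#' @return a prompt tibble with `prompt_type = "event_triggered"` and
#'   `linked_event_id` set; delivery state unresolved.
#' @export
trigger_event_prompts <- function(events, profile, delay_seconds = 60) {
  stopifnot(nrow(profile) == 1, delay_seconds >= 0)
  if (nrow(events) == 0) {
    return(new_prompts())
  }
  sent <- events$end_ts + delay_seconds
  w0 <- as.numeric(as_clock(profile$window_start))
  w1 <- as.numeric(as_clock(profile$window_end))
  cs <- clock_seconds(sent)
  keep <- cs >= w0 & cs <= w1
  sent <- sent[keep]
  new_prompts(
    prompt_id = sprintf(
      "%s-V%05d", profile$participant_id,
      seq_len(sum(keep))
    ),
    participant_id = profile$participant_id,
    prompt_type = "event_triggered",
    linked_event_id = events$event_id[keep],
    sent_ts = sent
  )
}

#' Resolve prompt delivery
#'
#' The scheduler sends prompts regardless of network state, but a prompt
#' reaches the phone only with probability `1 - failure_prob`. Received
#' prompts get `received_ts = sent_ts` (delivery latency is not modelled);
#' prompts that were sent but not received are excluded from all analyses
#' downstream.
#'
#' @param prompts a prompt tibble.
#' @param failure_prob probability in `[0, 1]` that a sent prompt is lost.
#' @param seed optional integer seed for reproducibility in isolation.
#' @return the prompt tibble with `received`/`received_ts` resolved.
#' @export
apply_delivery <- function(prompts, failure_prob, seed = NULL) {
  if (!is.numeric(failure_prob) || failure_prob < 0 || failure_prob > 1) {
    stop("failure_prob must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(prompts)
  rec <- runif(n) >= failure_prob
  prompts$received <- rec
  prompts$received_ts <- as.POSIXct(
    ifelse(rec, as.numeric(prompts$sent_ts), NA_real_),
    tz = .tz, origin = "1970-01-01"
  )
  prompts$answer_state <- ifelse(rec, NA_character_, "not_answered")
  prompts
}

#' The shipped EMA question catalogue
#'
#' Loads the versioned item catalogue (item batteries, response scales,
#' and the event-prompt branch structure) bundled with the package.
#'
#' @return a nested list mirroring the JSON resource.
#' @export
ema_items <- function() {
  path <- system.file("extdata", "ema_items.json", package = "emawear")
  if (path == "") {
    # during development (package not installed)
    path <- file.path("inst", "extdata", "ema_items.json")
  }
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Validate one prompt's responses against the question flow
#'
#' Checks branch reachability (for event prompts, items beyond the first
#' question must belong to the branch selected by the eating confirmation)
#' and response ranges (4-point ordinal items in 1-4, sliders in 0-100,
#' choice items among their options).
#'
#' @param prompt a single prompt row (one-row tibble or list) with
#'   `prompt_type`, `first_question_eating`, and `responses`.
#' @return list with `valid` (logical) and `violations` (character vector,
#'   empty when valid). Violations are reported, never raised.
#' @export
validate_flow <- function(prompt) {
  catalogue <- ema_items()
  responses <- prompt$responses
  if (is.data.frame(prompt)) responses <- prompt$responses[[1]]
  violations <- character()

  reachable <- flow_item_specs(catalogue, prompt$prompt_type,
    prompt$first_question_eating
  )
  for (key in names(responses)) {
    spec <- reachable[[key]]
    if (is.null(spec)) {
      violations <- c(violations, sprintf("item '%s' not reachable", key))
      next
    }
    val <- responses[[key]]
    if (identical(spec$scale, "ordinal4")) {
      if (!all(unlist(val) %in% 1:4)) {
        violations <- c(violations, sprintf("item '%s' outside 1-4 scale", key))
      }
    } else if (identical(spec$scale, "slider")) {
      v <- unlist(val)
      if (!is.numeric(v) || any(v < 0 | v > 100)) {
        violations <- c(
          violations,
          sprintf("item '%s' outside 0-100 slider range", key)
        )
      }
    } else if (!is.null(spec$options)) {
      if (!all(unlist(val) %in% unlist(spec$options))) {
        violations <- c(
          violations,
          sprintf("item '%s' has value outside its options", key)
        )
      }
    }
  }
  list(valid = length(violations) == 0, violations = violations)
}

# Flatten the catalogue into item_key -> spec for the reachable branch.
flow_item_specs <- function(catalogue, prompt_type, first_q) {
  expand <- function(item) {
    if (isTRUE(item$multi_item)) {
      ids <- if (!is.null(item$items)) {
        unlist(item$items)
      } else {
        unlist(catalogue$affect_items)
      }
      out <- stats::setNames(
        rep(list(list(scale = item$scale)), length(ids)),
        paste0(item$id, ".", ids)
      )
      out
    } else {
      stats::setNames(list(item), item$id)
    }
  }
  specs <- list()
  if (identical(prompt_type, "time_triggered")) {
    for (item in catalogue$time_triggered) specs <- c(specs, expand(item))
    return(specs)
  }
  fq <- catalogue$event_triggered$first_question
  specs[[fq$id]] <- fq
  branch_name <- if (identical(first_q, "yes")) {
    "yes"
  } else if (identical(first_q, "no")) {
    "no"
  } else {
    return(specs)
  }
  for (item in catalogue$event_triggered[[branch_name]]) {
    specs <- c(specs, expand(item))
  }
  specs
}
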