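# Synthetic family-deployment generator. Every downstream stage of the
# pipeline is exercised against these data, whose ground truth (true eating
# bouts, response propensities, true/false detection labels) is known by
# construction.

#' Simulate a participant roster
#'
#' Families contain one or two parents (mother and/or father) and one to
#' four participating children aged 11-18, reflecting eligibility rules for
#' in-home family deployments. Each participant receives a fixed
#' personalized daily participation window drawn within plausible waking
#' hours (start 06:00-09:00, end 21:00-24:00, whole minutes).
#'
#' @param config a [deployment_config()].
#' @param seed optional integer; when supplied the RNG is seeded so the
#'   roster is reproducible in isolation. Leave `NULL` when calling from a
#'   context that already manages the RNG (as [simulate_deployment()] does).
#' @return tibble with columns `participant_id`, `family_id`, `role`
#'   (`mother`/`father`/`child`), `gender` (`female`/`male`), `age_years`,
#'   `height_cm`, `window_start`, `window_end` (hms).
#' @export
simulate_roster <- function(config, seed = config$random_seed) {
  validate_deployment_config(config)
  if (!is.null(seed)) set.seed(seed)

  fam <- function(i) {
    family_id <- sprintf("F%02d", i)
    two_parent <- runif(1) < 0.85
    parent_roles <- if (two_parent) {
      c("mother", "father")
    } else if (runif(1) < 0.8) "mother" else "father"
    n_children <- sample(1:4, 1, prob = c(0.15, 0.75, 0.05, 0.05))
    roles <- c(parent_roles, rep("child", n_children))
    gender <- ifelse(
      roles == "mother", "female",
      ifelse(roles == "father", "male",
        ifelse(runif(length(roles)) < 0.4, "female", "male")
      )
    )
    age <- ifelse(
      roles == "child",
      sample(11:18, length(roles), replace = TRUE),
      pmin(pmax(round(rnorm(length(roles), 43.7, 6.7), 1), 25), 70)
    )
    height <- ifelse(
      roles == "child", rnorm(length(roles), 160, 12),
      ifelse(gender == "female", rnorm(length(roles), 162, 7),
        rnorm(length(roles), 176, 8)
      )
    )
    w_start <- sample(seq(6 * 3600, 9 * 3600, by = 60), length(roles),
      replace = TRUE
    )
    w_end <- sample(seq(21 * 3600, 24 * 3600 - 60, by = 60), length(roles),
      replace = TRUE
    )
    tibble::tibble(
      participant_id = sprintf("%s-P%d", family_id, seq_along(roles)),
      family_id = family_id,
      role = roles,
      gender = gender,
      age_years = age,
      height_cm = round(pmax(height, 120), 1),
      window_start = hms::as_hms(w_start),
      window_end = hms::as_hms(w_end)
    )
  }
  dplyr::bind_rows(lapply(seq_len(config$n_families), fam))
}

# Place `n` non-conflicting half-open spans of the given durations inside
# [lo, hi], keeping >= `gap` seconds between spans. Retries each span; on
# repeated failure (crowded window) the span is dropped.
place_spans <- function(n, durations, lo, hi, gap = 61, max_try = 100) {
  starts <- numeric(0)
  ends <- numeric(0)
  for (i in seq_len(n)) {
    d <- durations[i]
    if (hi - lo < d) next
    for (attempt in seq_len(max_try)) {
      s <- runif(1, lo, hi - d)
      if (all(s > ends + gap | s + d < starts - gap)) {
        starts <- c(starts, s)
        ends <- c(ends, s + d)
        break
      }
    }
  }
  ord <- order(starts)
  list(start = starts[ord], end = ends[ord])
}

#' Simulate one participant's gesture stream
#'
#' Eating bouts arrive as a homogeneous Poisson process within the
#' participant's daily window; each bout emits hand-to-mouth gestures at
#' uniform 2-20 s gaps (config-exposed), so every bout contains at least
#' two gestures within 60 s and is detectable by construction. Noise
#' gestures (phone use and similar) are isolated single gestures placed
#' more than 60 s from any other gesture; optional noise *bursts* are
#' clusters of 2-4 non-eating gestures that survive detection and provide
#' the simulator's false-positive mechanism.
#'
#' @inheritParams simulate_roster
#' @param profile one roster row (see [simulate_roster()]).
#' @return list with `gestures` (tibble `participant_id`, `timestamp`,
#'   `source` in `bout`/`noise`/`noise_burst`, `bout_id`) and `bouts`
#'   (tibble `bout_id`, `participant_id`, `start_ts`, `end_ts`,
#'   `n_gestures`), the ground-truth eating bouts.
#' @export
simulate_gestures <- function(profile, config, seed = NULL) {
  validate_deployment_config(config)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(profile) == 1)
  w0 <- as.numeric(profile$window_start)
  w1 <- as.numeric(profile$window_end)

  all_ts <- numeric(0)
  all_src <- character(0)
  all_bout <- character(0)
  bout_rows <- list()
  bout_n <- 0L

  for (day in seq_len(config$deployment_days)) {
    day0 <- as.numeric(day_time(config$start_date, day, 0))
    # eating bouts
    nb <- rpois(1, config$eating_bouts_per_person_day)
    durs <- runif(nb, config$bout_duration_minutes[1] * 60,
      config$bout_duration_minutes[2] * 60
    )
    spans <- place_spans(nb, durs, day0 + w0, day0 + w1)
    for (k in seq_along(spans$start)) {
      t <- spans$start[k]
      ts <- t
      while (TRUE) {
        t <- t + runif(1, config$gesture_gap_seconds[1],
          config$gesture_gap_seconds[2]
        )
        if (t > spans$end[k]) break
        ts <- c(ts, t)
      }
      ts <- round(ts)
      bout_n <- bout_n + 1L
      bid <- sprintf("%s-B%04d", profile$participant_id, bout_n)
      all_ts <- c(all_ts, ts)
      all_src <- c(all_src, rep("bout", length(ts)))
      all_bout <- c(all_bout, rep(bid, length(ts)))
      bout_rows[[bout_n]] <- tibble::tibble(
        bout_id = bid,
        participant_id = profile$participant_id,
        start_ts = as.POSIXct(min(ts), tz = .tz, origin = "1970-01-01"),
        end_ts = as.POSIXct(max(ts), tz = .tz, origin = "1970-01-01"),
        n_gestures = length(ts)
      )
    }
    # isolated noise gestures: > 60 s from everything already placed today
    window_hours <- (w1 - w0) / 3600
    nn <- rpois(1, config$noise_gesture_rate * window_hours)
    day_ts <- all_ts[all_ts >= day0 & all_ts < day0 + 86400]
    for (k in seq_len(nn)) {
      for (attempt in seq_len(100)) {
        t <- round(runif(1, day0 + w0, day0 + w1))
        if (all(abs(t - day_ts) > 60)) {
          all_ts <- c(all_ts, t)
          all_src <- c(all_src, "noise")
          all_bout <- c(all_bout, NA_character_)
          day_ts <- c(day_ts, t)
          break
        }
      }
    }
    # noise bursts: clustered non-eating gestures (false-positive mechanism)
    nburst <- rpois(1, config$noise_burst_rate)
    for (k in seq_len(nburst)) {
      ng <- sample(2:4, 1)
      gaps <- runif(ng - 1, config$gesture_gap_seconds[1],
        config$gesture_gap_seconds[2]
      )
      span <- sum(gaps)
      for (attempt in seq_len(100)) {
        t0 <- runif(1, day0 + w0, max(day0 + w0 + 1, day0 + w1 - span))
        ts <- round(t0 + c(0, cumsum(gaps)))
        if (all(vapply(ts, function(x) all(abs(x - day_ts) > 60), logical(1)))) {
          all_ts <- c(all_ts, ts)
          all_src <- c(all_src, rep("noise_burst", ng))
          all_bout <- c(all_bout, rep(NA_character_, ng))
          day_ts <- c(day_ts, ts)
          break
        }
      }
    }
  }

  ord <- order(all_ts)
  gestures <- tibble::tibble(
    participant_id = profile$participant_id,
    timestamp = as.POSIXct(all_ts[ord], tz = .tz, origin = "1970-01-01"),
    source = all_src[ord],
    bout_id = all_bout[ord]
  )
  bouts <- if (bout_n > 0) {
    dplyr::arrange(dplyr::bind_rows(bout_rows), .data$start_ts)
  } else {
    tibble::tibble(
      bout_id = character(), participant_id = character(),
      start_ts = empty_timestamp(), end_ts = empty_timestamp(),
      n_gestures = integer()
    )
  }
  list(gestures = gestures, bouts = bouts)
}

#' Simulate per-minute sensor availability
#'
#' Emits one record per minute of each deployment day inside the
#' participant's window. Outside eating bouts, accelerometer availability,
#' movement (given availability), and beacon availability are independent
#' Bernoulli draws at the configured per-minute probabilities — their gaps
#' stand in for watch-off and out-of-home periods. Minutes overlapping a
#' true eating bout are fully sensed with probability `bout_sensor_prob`
#' (the participant is wearing the watch and moving while eating at home).
#'
#' @inheritParams simulate_gestures
#' @param bouts ground-truth bout tibble from [simulate_gestures()].
#' @return tibble `participant_id`, `minute_start` (POSIXct, minute
#'   aligned), `accel_available`, `movement`, `beacon_available`.
#' @export
simulate_sensor_minutes <- function(profile, bouts, config, seed = NULL) {
  validate_deployment_config(config)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nrow(profile) == 1)
  w0 <- floor(as.numeric(profile$window_start) / 60) * 60
  # window ends are inclusive (a prompt may arrive exactly at window_end),
  # so the minute containing window_end belongs to the window
  w1 <- floor(as.numeric(profile$window_end) / 60) * 60

  mins <- unlist(lapply(seq_len(config$deployment_days), function(day) {
    day0 <- as.numeric(day_time(config$start_date, day, 0))
    seq(day0 + w0, day0 + w1, by = 60)
  }))
  n <- length(mins)
  accel <- runif(n) < config$accel_available_prob
  movement <- accel & (runif(n) < config$movement_prob)
  beacon <- runif(n) < config$beacon_available_prob

  if (nrow(bouts) > 0) {
    bs <- as.numeric(bouts$start_ts)
    be <- as.numeric(bouts$end_ts)
    overlaps <- vapply(
      mins,
      function(m) any(bs < m + 60 & be >= m),
      logical(1)
    )
    sensed <- overlaps & (runif(n) < config$bout_sensor_prob)
    accel[sensed] <- TRUE
    movement[sensed] <- TRUE
    beacon[sensed] <- TRUE
  }

  tibble::tibble(
    participant_id = profile$participant_id,
    minute_start = as.POSIXct(mins, tz = .tz, origin = "1970-01-01"),
    accel_available = accel,
    movement = movement,
    beacon_available = beacon
  )
}

#' Simulate answer behaviour for delivered prompts
#'
#' Walks the received prompts in timestamp order and answers each with
#' probability `plogis(eta)`, where `eta` is the configured response-model
#' linear predictor evaluated on the prompt's covariates (time-of-day bin,
#' weekend, deployment day, age, gender, family role, and whether another
#' family member has already answered a prompt received within 15 minutes).
#' Answered event-triggered prompts get their first question ("eating or
#' drinking just now?") answered yes with `confirm_true_event_prob` when
#' the triggering detection overlaps a true bout and with
#' `confirm_false_event_prob` otherwise; full item responses are filled in
#' for answered prompts according to the shipped question catalogue.
#'
#' @inheritParams simulate_roster
#' @param prompts prompt tibble with delivery state resolved
#'   (see [apply_delivery()]).
#' @param roster roster tibble.
#' @param event_truth optional tibble `event_id`, `true_event` (logical)
#'   labelling the detections behind event-triggered prompts; required when
#'   any event-triggered prompt is present.
#' @return the prompt tibble with `answer_state`, `first_question_eating`,
#'   and `responses` filled, plus a `propensity` column holding each
#'   received prompt's true answer probability (ground truth for
#'   parameter-recovery tests).
#' @export
simulate_responses <- function(prompts, roster, config, event_truth = NULL,
                               seed = NULL) {
  validate_deployment_config(config)
  if (!is.null(seed)) set.seed(seed)
  if (any(is.na(prompts$received))) {
    stop("prompts have unresolved delivery state; run apply_delivery() first",
      call. = FALSE
    )
  }
  if (any(prompts$prompt_type == "event_triggered") && is.null(event_truth)) {
    stop("event_truth required when event-triggered prompts are present",
      call. = FALSE
    )
  }

  coefs <- config$response_model
  prompts <- prompts |>
    dplyr::left_join(
      roster[, c("participant_id", "family_id", "role", "gender", "age_years")],
      by = "participant_id"
    ) |>
    dplyr::arrange(.data$sent_ts, .data$prompt_id)
  if (!is.null(event_truth)) {
    prompts <- dplyr::left_join(
      prompts, event_truth[, c("event_id", "true_event")],
      by = c("linked_event_id" = "event_id")
    )
  } else {
    prompts$true_event <- NA
  }

  n <- nrow(prompts)
  answered <- logical(n)
  propensity <- rep(NA_real_, n)
  answer_state <- rep("not_answered", n)
  first_q <- rep(NA_character_, n)
  responses <- vector("list", n)

  secs <- clock_seconds(prompts$received_ts)
  afternoon <- !is.na(secs) & secs >= 12 * 3600 & secs < 17 * 3600
  evening <- !is.na(secs) & secs >= 17 * 3600
  weekend <- !is.na(prompts$received_ts) &
    lubridate::wday(prompts$received_ts, week_start = 1) >= 6
  dep_day <- 1 + floor(
    (as.numeric(prompts$received_ts) -
      as.numeric(as.POSIXct(config$start_date, tz = .tz))) / 86400
  )
  et_coef <- if ("event_triggered" %in% names(coefs)) {
    coefs[["event_triggered"]]
  } else {
    0
  }

  catalogue <- ema_items()
  rec_t <- as.numeric(prompts$received_ts)
  # received rows are sorted by received_ts (= sent_ts), so the +/-15 min
  # social window can be located with findInterval instead of a full scan
  rec_idx <- which(prompts$received)
  rt <- rec_t[rec_idx]

  for (i in seq_len(n)) {
    if (!prompts$received[i]) next
    lo <- findInterval(rec_t[i] - 15 * 60, rt, left.open = TRUE) + 1
    hi <- findInterval(rec_t[i] + 15 * 60, rt)
    cand <- rec_idx[seq.int(lo, hi)]
    others <- cand[
      answered[cand] &
        prompts$family_id[cand] == prompts$family_id[i] &
        prompts$participant_id[cand] != prompts$participant_id[i]
    ]
    eta <- coefs[["intercept"]] +
      coefs[["age_years"]] * prompts$age_years[i] +
      coefs[["afternoon"]] * afternoon[i] +
      coefs[["evening"]] * evening[i] +
      coefs[["weekend"]] * weekend[i] +
      coefs[["deployment_day"]] * dep_day[i] +
      coefs[["female"]] * (prompts$gender[i] == "female") +
      coefs[["mother"]] * (prompts$role[i] == "mother") +
      coefs[["father"]] * (prompts$role[i] == "father") +
      coefs[["others_answered"]] * (length(others) > 0) +
      et_coef * (prompts$prompt_type[i] == "event_triggered")
    p <- plogis(eta)
    propensity[i] <- p
    if (runif(1) >= p) next
    answered[i] <- TRUE
    complete <- runif(1) < config$complete_given_answered_prob
    answer_state[i] <- if (complete) "complete" else "partial"
    if (prompts$prompt_type[i] == "event_triggered") {
      p_yes <- if (isTRUE(prompts$true_event[i])) {
        config$confirm_true_event_prob
      } else {
        config$confirm_false_event_prob
      }
      first_q[i] <- if (runif(1) < p_yes) "yes" else "no"
    }
    responses[[i]] <- draw_responses(
      catalogue, prompts$prompt_type[i], first_q[i], complete
    )
  }

  prompts$answer_state <- answer_state
  prompts$first_question_eating <- first_q
  prompts$responses <- responses
  prompts$propensity <- propensity
  prompts[, !(names(prompts) %in%
    c("family_id", "role", "gender", "age_years", "true_event"))]
}

# Draw a plausible response set for one answered prompt. Partial answers
# truncate the battery after the first item (event prompts always retain
# the first question).
draw_responses <- function(catalogue, prompt_type, first_q, complete) {
  draw_item <- function(item) {
    if (isTRUE(item$multi_item)) {
      ids <- if (!is.null(item$items)) item$items else catalogue$affect_items
      stats::setNames(
        as.list(sample(1:4, length(ids), replace = TRUE)),
        paste0(item$id, ".", ids)
      )
    } else if (!is.null(item$scale) && item$scale == "slider") {
      stats::setNames(list(sample(0:100, 1)), item$id)
    } else if (isTRUE(item$multi_select)) {
      stats::setNames(
        list(sample(unlist(item$options), sample(1:2, 1))), item$id
      )
    } else if (isTRUE(item$free_text)) {
      stats::setNames(
        list(sample(c(
          "using my phone", "smoking", "fixing my hair",
          "putting on lotion", "other"
        ), 1)),
        item$id
      )
    } else {
      stats::setNames(list(sample(unlist(item$options), 1)), item$id)
    }
  }
  if (prompt_type == "time_triggered") {
    battery <- catalogue$time_triggered
    resp <- list()
    for (item in battery) resp <- c(resp, draw_item(item))
    if (!complete) resp <- resp[seq_len(min(3, length(resp)))]
    return(resp)
  }
  resp <- list(eating_confirmation = first_q)
  if (!complete) {
    return(resp)
  }
  branch <- catalogue$event_triggered[[first_q]]
  for (item in branch) resp <- c(resp, draw_item(item))
  resp
}

#' Label detected events against ground-truth bouts
#'
#' A detection is a true event iff its `[start_ts, end_ts]` span overlaps
#' any ground-truth bout of the same participant.
#'
#' @param events detected-event tibble (see [detect_eating_events()]).
#' @param bouts ground-truth bout tibble.
#' @return tibble `event_id`, `true_event`.
#' @export
truth_labels <- function(events, bouts) {
  lab <- vapply(seq_len(nrow(events)), function(i) {
    b <- bouts[bouts$participant_id == events$participant_id[i], ]
    any(as.numeric(b$start_ts) <= as.numeric(events$end_ts[i]) &
      as.numeric(b$end_ts) >= as.numeric(events$start_ts[i]))
  }, logical(1))
  tibble::tibble(event_id = events$event_id, true_event = lab)
}

#' Simulate a complete family deployment
#'
#' Runs the full generative pipeline: roster, gesture streams, sensor
#' minutes, eating-event detection, at-home filtering, prompt scheduling,
#' delivery, and response simulation. Seeded once from
#' `config$random_seed`, so identical configurations give identical output.
#'
#' @param config a [deployment_config()].
#' @return list with tibbles `roster`, `gestures`, `bouts`,
#'   `sensor_minutes`, `events` (at-home detections), `event_truth`,
#'   `prompts`, and the `config` used.
#' @export
simulate_deployment <- function(config = deployment_config()) {
  validate_deployment_config(config)
  set.seed(config$random_seed)

  roster <- simulate_roster(config, seed = NULL)
  gestures <- list()
  bouts <- list()
  minutes <- list()
  events <- list()
  prompts <- list()

  for (i in seq_len(nrow(roster))) {
    profile <- roster[i, ]
    g <- simulate_gestures(profile, config, seed = NULL)
    m <- simulate_sensor_minutes(profile, g$bouts, config, seed = NULL)
    ev <- detect_eating_events(g$gestures)
    ev <- filter_at_home_events(ev, m)
    tp <- schedule_time_triggered(profile, config$deployment_days,
      start_date = config$start_date
    )
    ep <- trigger_event_prompts(ev, profile,
      delay_seconds = config$event_prompt_delay_seconds
    )
    gestures[[i]] <- g$gestures
    bouts[[i]] <- g$bouts
    minutes[[i]] <- m
    events[[i]] <- ev
    prompts[[i]] <- dplyr::bind_rows(tp, ep)
  }

  gestures <- dplyr::bind_rows(gestures)
  bouts <- dplyr::bind_rows(bouts)
  minutes <- dplyr::bind_rows(minutes)
  events <- dplyr::bind_rows(events)
  prompts <- dplyr::bind_rows(prompts)

  prompts <- apply_delivery(prompts, config$prompt_delivery_failure_prob,
    seed = NULL
  )
  event_truth <- truth_labels(events, bouts)
  prompts <- simulate_responses(prompts, roster, config,
    event_truth = event_truth, seed = NULL
  )

  list(
    roster = roster, gestures = gestures, bouts = bouts,
    sensor_minutes = minutes, events = events, event_truth = event_truth,
    prompts = prompts, config = config
  )
}
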