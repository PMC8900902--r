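# Shared fixtures and independent brute-force oracles.

tz_utc <- "UTC"

ts_at <- function(x) as.POSIXct(x, tz = tz_utc)

tiny_config <- function(...) {
  deployment_config(
    n_families = 2, deployment_days = 3, eating_bouts_per_person_day = 1,
    random_seed = 7L, ...
  )
}

# A minimal resolved prompt tibble: n_answered answered, the rest received
# but unanswered, plus n_lost sent-but-not-received rows.
make_prompts <- function(n_answered, n_unanswered, n_lost = 0,
                         participant_id = "p1",
                         prompt_type = "time_triggered",
                         t0 = ts_at("2024-03-04 08:00:00"),
                         spacing = 3600) {
  n <- n_answered + n_unanswered + n_lost
  sent <- t0 + spacing * (seq_len(n) - 1)
  received <- rep(c(TRUE, FALSE), c(n_answered + n_unanswered, n_lost))
  link_ids <- if (identical(prompt_type, "event_triggered")) {
    sprintf("%s-E%05d", participant_id, seq_len(n))
  } else {
    rep(NA_character_, n)
  }
  tibble::tibble(
    prompt_id = sprintf("%s-%05d", participant_id, seq_len(n)),
    participant_id = participant_id,
    prompt_type = prompt_type,
    linked_event_id = link_ids,
    sent_ts = sent,
    received = received,
    received_ts = as.POSIXct(ifelse(received, as.numeric(sent), NA_real_),
      tz = tz_utc, origin = "1970-01-01"
    ),
    answer_state = rep(c("complete", "not_answered", "not_answered"),
      c(n_answered, n_unanswered, n_lost)
    ),
    first_question_eating = NA_character_,
    responses = vector("list", n)
  )
}

# Event-triggered prompts with known outcome labels:
# "tp" answered yes, "fp" answered no, "unv" not answered.
event_prompts_fixture <- function(labels, pid = "p1") {
  n <- length(labels)
  p <- make_prompts(n, 0, participant_id = pid, prompt_type = "event_triggered")
  p$first_question_eating <- ifelse(labels == "tp", "yes",
    ifelse(labels == "fp", "no", NA_character_)
  )
  p$answer_state[labels == "unv"] <- "not_answered"
  p$responses <- lapply(labels, function(l) {
    if (l == "fp") {
      list(eating_confirmation = "no", activity = "using my phone")
    } else {
      NULL
    }
  })
  p
}

one_profile <- function(window_start = "06:30:00", window_end = "23:00:00") {
  tibble::tibble(
    participant_id = "p1", family_id = "f1", role = "mother",
    gender = "female", age_years = 40, height_cm = 165,
    window_start = hms::as_hms(window_start),
    window_end = hms::as_hms(window_end)
  )
}

# Transitive-closure clustering oracle: union all pairs of gestures within
# `window` seconds until a fixed point, then report components with at
# least `min_gestures` members.
oracle_cluster <- function(ts, window = 60, min_gestures = 2) {
  n <- length(ts)
  if (n == 0) {
    return(list())
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (abs(ts[i] - ts[j]) <= window && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- list()
  for (c_id in unique(comp)) {
    member <- ts[comp == c_id]
    if (length(member) >= min_gestures) {
      out[[length(out) + 1]] <- c(min(member), max(member), length(member))
    }
  }
  out[order(vapply(out, `[`, numeric(1), 1))]
}

# Per-minute membership indicator for a set of half-open intervals.
oracle_minute_indicator <- function(minute_starts, start, end) {
  vapply(minute_starts, function(m) {
    any(m >= as.numeric(start) & m < as.numeric(end))
  }, logical(1))
}

# Mann-Whitney U as pairwise wins plus half-ties for group x over group y.
oracle_u_statistic <- function(x, y) {
  u <- 0
  for (xi in x) {
    for (yj in y) {
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    }
  }
  u
}

# Direct logistic maximum likelihood by Newton-Raphson on the given design
# matrix (intercept included as the first column).
oracle_logistic_irls <- function(X, y, tol = 1e-10, max_iter = 50) {
  beta <- rep(0, ncol(X))
  for (iter in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    W <- p * (1 - p)
    score <- drop(t(X) %*% (y - p))
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}
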