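#' Deployment configuration
#'
#' Builds and validates the configuration object that drives the synthetic
#' deployment generator and the pipeline. Defaults describe a realistic
#' two-week, 20-family in-home deployment.
#'
#' @param n_families positive integer, number of families to simulate.
#' @param deployment_days positive integer, consecutive days per family.
#' @param start_date first deployment day (Date or string); all families
#'   share it.
#' @param eating_bouts_per_person_day expected number of at-home eating
#'   bouts per person per day (Poisson rate).
#' @param bout_duration_minutes length-2 numeric, uniform range of bout
#'   durations in minutes.
#' @param gesture_gap_seconds length-2 numeric, uniform range of
#'   within-bout gaps between consecutive hand-to-mouth gestures (seconds).
#'   The upper bound must stay below `60` so every simulated bout satisfies
#'   the two-gestures-within-a-minute detection rule.
#' @param noise_gesture_rate expected isolated non-eating gestures per hour
#'   (phone use and similar); isolated means > 60 s from any other gesture.
#' @param noise_burst_rate expected non-eating gesture *bursts* per person
#'   per day. A burst contains >= 2 clustered gestures, so it survives
#'   detection and yields a false-positive event; 0 disables false positives.
#' @param accel_available_prob,movement_prob,beacon_available_prob per-minute
#'   probabilities of accelerometer availability, of movement given
#'   availability, and of beacon availability, outside eating bouts.
#' @param bout_sensor_prob probability that a minute overlapping an eating
#'   bout is fully sensed (accelerometer available, movement, beacon).
#' @param prompt_delivery_failure_prob probability a sent prompt is never
#'   received by the phone.
#' @param response_model named numeric vector of log-odds coefficients for
#'   the response (compliance) model; see [reference_model_coefficients()]
#'   for the expected names.
#' @param complete_given_answered_prob probability an answered prompt is
#'   fully rather than partially completed (bookkeeping only; both count as
#'   answered).
#' @param confirm_true_event_prob probability the first event-prompt
#'   question is answered "yes" when the detection overlaps a true bout.
#' @param confirm_false_event_prob same when it does not (self-report error).
#' @param event_prompt_delay_seconds delay from detected event end to the
#'   event-triggered prompt.
#' @param anchor_radius_minutes half-width of the participation interval
#'   anchored on each answered prompt.
#' @param random_seed integer seed recorded in the configuration.
#' @return a validated list with class `"deployment_config"`.
#' @export
deployment_config <- function(n_families = 20,
                              deployment_days = 14,
                              start_date = "2024-03-04",
                              eating_bouts_per_person_day = 1,
                              bout_duration_minutes = c(2, 20),
                              gesture_gap_seconds = c(2, 20),
                              noise_gesture_rate = 0.3,
                              noise_burst_rate = 0.15,
                              accel_available_prob = 0.75,
                              movement_prob = 0.6,
                              beacon_available_prob = 0.85,
                              bout_sensor_prob = 1,
                              prompt_delivery_failure_prob = 0.1,
                              response_model = reference_model_coefficients("all"),
                              complete_given_answered_prob = 0.9,
                              confirm_true_event_prob = 0.95,
                              confirm_false_event_prob = 0.05,
                              event_prompt_delay_seconds = 60,
                              anchor_radius_minutes = 15,
                              random_seed = 1L) {
  cfg <- list(
    n_families = n_families,
    deployment_days = deployment_days,
    start_date = as.Date(start_date),
    eating_bouts_per_person_day = eating_bouts_per_person_day,
    bout_duration_minutes = bout_duration_minutes,
    gesture_gap_seconds = gesture_gap_seconds,
    noise_gesture_rate = noise_gesture_rate,
    noise_burst_rate = noise_burst_rate,
    accel_available_prob = accel_available_prob,
    movement_prob = movement_prob,
    beacon_available_prob = beacon_available_prob,
    bout_sensor_prob = bout_sensor_prob,
    prompt_delivery_failure_prob = prompt_delivery_failure_prob,
    response_model = response_model,
    complete_given_answered_prob = complete_given_answered_prob,
    confirm_true_event_prob = confirm_true_event_prob,
    confirm_false_event_prob = confirm_false_event_prob,
    event_prompt_delay_seconds = event_prompt_delay_seconds,
    anchor_radius_minutes = anchor_radius_minutes,
    random_seed = as.integer(random_seed)
  )
  validate_deployment_config(cfg)
  structure(cfg, class = "deployment_config")
}

validate_deployment_config <- function(cfg) {
  chk_count <- function(field, minimum = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < minimum ||
      v != round(v)) {
      stop(sprintf("config field '%s' must be an integer >= %s", field, minimum),
        call. = FALSE
      )
    }
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("config field '%s' must be a probability in [0, 1]", field),
        call. = FALSE
      )
    }
  }
  chk_nonneg <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop(sprintf("config field '%s' must be a non-negative number", field),
        call. = FALSE
      )
    }
  }
  chk_count("n_families")
  chk_count("deployment_days")
  chk_nonneg("eating_bouts_per_person_day")
  chk_nonneg("noise_gesture_rate")
  chk_nonneg("noise_burst_rate")
  chk_nonneg("event_prompt_delay_seconds")
  chk_count("anchor_radius_minutes")
  for (f in c(
    "accel_available_prob", "movement_prob", "beacon_available_prob",
    "bout_sensor_prob", "prompt_delivery_failure_prob",
    "complete_given_answered_prob", "confirm_true_event_prob",
    "confirm_false_event_prob"
  )) {
    chk_prob(f)
  }
  rng <- cfg$bout_duration_minutes
  if (!is.numeric(rng) || length(rng) != 2 || rng[1] <= 0 || rng[1] > rng[2]) {
    stop("config field 'bout_duration_minutes' must be an increasing positive pair",
      call. = FALSE
    )
  }
  gap <- cfg$gesture_gap_seconds
  if (!is.numeric(gap) || length(gap) != 2 || gap[1] <= 0 || gap[1] > gap[2] ||
    gap[2] >= 60) {
    stop("config field 'gesture_gap_seconds' must be an increasing pair below 60",
      call. = FALSE
    )
  }
  coefs <- cfg$response_model
  missing_terms <- setdiff(model_term_names(), names(coefs))
  if (length(missing_terms) > 0) {
    stop(
      "config field 'response_model' is missing coefficients: ",
      paste(missing_terms, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(cfg)
}

model_term_names <- function() {
  c(
    "intercept", "age_years", "afternoon", "evening", "weekend",
    "deployment_day", "female", "mother", "father", "others_answered"
  )
}

#' Published reference coefficient sets for the compliance models
#'
#' Log-odds coefficients reported from an in-field family EMA deployment,
#' for the three compliance models: pooled over all prompts,
#' time-triggered prompts only, and eating event-triggered prompts only.
#' Reference categories: morning, weekday, male, child role,
#' others-answered no. The pooled set additionally carries an
#' `event_triggered` prompt-type indicator, whose reference value is not
#' published; it defaults to 0 here and exists so that simulated pooled
#' data exercise the same design as the pooled fit.
#'
#' These vectors are the canonical inputs for simulation-based
#' parameter-recovery experiments (see [simulate_observations()]).
#'
#' @param model one of `"all"`, `"time_triggered"`, `"event_triggered"`.
#' @return named numeric vector of log-odds coefficients.
#' @export
#' @examples
#' exp(reference_model_coefficients("time_triggered")["others_answered"])
reference_model_coefficients <- function(model = c(
                                           "all", "time_triggered",
                                           "event_triggered"
                                         )) {
  model <- match.arg(model)
  switch(model,
    all = c(
      intercept = 2.17, age_years = 0.00, afternoon = -0.47,
      evening = -0.50, weekend = 0.06, deployment_day = -0.02,
      female = 0.19, mother = -0.01, father = -0.42,
      others_answered = 0.65, event_triggered = 0
    ),
    time_triggered = c(
      intercept = 2.22, age_years = 0.00, afternoon = -0.51,
      evening = -0.63, weekend = -0.06, deployment_day = -0.01,
      female = 0.31, mother = 0.06, father = -0.37,
      others_answered = 0.73
    ),
    event_triggered = c(
      intercept = 2.41, age_years = 0.02, afternoon = -0.35,
      evening = 0.28, weekend = 0.87, deployment_day = -0.09,
      female = -0.65, mother = -0.65, father = -0.64,
      others_answered = -0.02
    )
  )
}

#' @export
print.deployment_config <- function(x, ...) {
  cat("<deployment_config>\n")
  cat(sprintf(
    "  %d families x %d days from %s (seed %d)\n",
    x$n_families, x$deployment_days, format(x$start_date), x$random_seed
  ))
  cat(sprintf(
    "  bouts/person-day %.2f, noise %.2f/h, bursts %.2f/day\n",
    x$eating_bouts_per_person_day, x$noise_gesture_rate, x$noise_burst_rate
  ))
  cat(sprintf(
    "  delivery failure %.2f, confirm true/false %.2f/%.2f\n",
    x$prompt_delivery_failure_prob, x$confirm_true_event_prob,
    x$confirm_false_event_prob
  ))
  invisible(x)
}

#' Read or write a deployment configuration as YAML or JSON
#'
#' @param path file path ending in `.yaml`, `.yml`, or `.json`.
#' @return for `read_deployment_config()`, a `deployment_config`.
#' @export
read_deployment_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  raw$response_model <- unlist(raw$response_model)
  do.call(deployment_config, raw)
}

#' @param config a `deployment_config`.
#' @rdname read_deployment_config
#' @export
write_deployment_config <- function(config, path) {
  x <- unclass(config)
  x$start_date <- format(x$start_date)
  x$response_model <- as.list(x$response_model)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
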