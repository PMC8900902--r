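test_that("roster satisfies family composition rules and is seed-deterministic", {
  cfg <- deployment_config(n_families = 1, random_seed = 1L)
  roster <- simulate_roster(cfg)

  expect_gte(nrow(roster), 2)
  expect_true(any(roster$role %in% c("mother", "father")))
  kids <- roster[roster$role == "child", ]
  expect_gte(nrow(kids), 1)
  expect_true(all(kids$age_years >= 11 & kids$age_years <= 18))
  expect_identical(unique(roster$family_id), "F01")

  expect_identical(roster, simulate_roster(cfg))

  big <- simulate_roster(deployment_config(n_families = 20, random_seed = 7L))
  expect_identical(length(unique(big$family_id)), 20L)
  # each participant belongs to exactly one family
  expect_identical(anyDuplicated(big$participant_id), 0L)
  per_fam <- split(big$role, big$family_id)
  expect_true(all(vapply(per_fam, function(r) any(r == "child"), logical(1))))
  expect_true(all(vapply(
    per_fam, function(r) any(r %in% c("mother", "father")), logical(1)
  )))
  # windows within plausible waking hours
  expect_true(all(big$window_start >= hms::as_hms("06:00:00")))
  expect_true(all(big$window_end <= hms::as_hms("24:00:00")))
  expect_true(all(big$window_start < big$window_end))
})

test_that("family sizes follow the configured distribution over many seeds", {
  sizes <- unlist(lapply(1:40, function(s) {
    r <- simulate_roster(deployment_config(n_families = 5, random_seed = s))
    as.vector(table(r$family_id))
  }))
  # expected size = P(2 parents)*2 + 1*0.15 + E[children] = 1.85 + 2
  expected <- 0.85 * 2 + 0.15 * 1 + sum(1:4 * c(0.15, 0.75, 0.05, 0.05))
  se <- sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})

test_that("gesture stream labels are conserved and respect noise settings", {
  profile <- one_profile()

  no_noise <- simulate_gestures(
    profile,
    deployment_config(noise_gesture_rate = 0, noise_burst_rate = 0),
    seed = 11
  )
  expect_true(all(no_noise$gestures$source == "bout"))
  expect_true(all(!is.na(no_noise$gestures$bout_id)))
  expect_identical(
    sum(no_noise$bouts$n_gestures), nrow(no_noise$gestures)
  )

  no_bouts <- simulate_gestures(
    profile,
    deployment_config(eating_bouts_per_person_day = 0, noise_gesture_rate = 2),
    seed = 11
  )
  expect_identical(nrow(no_bouts$bouts), 0L)
  expect_true(all(no_bouts$gestures$source == "noise"))

  mixed <- simulate_gestures(profile, deployment_config(), seed = 12)
  expect_identical(
    nrow(mixed$gestures),
    sum(mixed$gestures$source == "bout") +
      sum(mixed$gestures$source != "bout")
  )
  expect_identical(sum(mixed$bouts$n_gestures), sum(mixed$gestures$source == "bout"))
  # all gestures inside the participation window
  secs <- as.numeric(mixed$gestures$timestamp) %% 86400
  expect_true(all(secs >= as.numeric(profile$window_start)))
  expect_true(all(secs <= as.numeric(profile$window_end)))
})

test_that("bout arrivals match the configured Poisson rate", {
  cfg <- deployment_config(
    eating_bouts_per_person_day = 3, deployment_days = 14,
    noise_gesture_rate = 0, noise_burst_rate = 0
  )
  profile <- one_profile()
  counts <- vapply(
    1:60,
    function(s) nrow(simulate_gestures(profile, cfg, seed = s)$bouts),
    numeric(1)
  )
  expected <- 3 * 14
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("sensor minutes cover the window and hit configured availability", {
  profile <- one_profile("08:00:00", "22:00:00")
  bouts <- tibble::tibble(
    bout_id = character(), participant_id = character(),
    start_ts = ts_at(character()), end_ts = ts_at(character()),
    n_gestures = integer()
  )

  all_on <- simulate_sensor_minutes(
    profile, bouts,
    deployment_config(
      accel_available_prob = 1, movement_prob = 1,
      beacon_available_prob = 1, deployment_days = 2
    ),
    seed = 3
  )
  expect_identical(nrow(all_on), 2L * (14L * 60L + 1L))
  expect_true(all(classify_minute(all_on)))

  all_off <- simulate_sensor_minutes(
    profile, bouts,
    deployment_config(accel_available_prob = 0, deployment_days = 2),
    seed = 3
  )
  expect_false(any(classify_minute(all_off)))

  cfg80 <- deployment_config(
    accel_available_prob = 0.8, deployment_days = 14,
    eating_bouts_per_person_day = 0
  )
  mins <- dplyr::bind_rows(lapply(1:15, function(s) {
    simulate_sensor_minutes(profile, bouts, cfg80, seed = s)
  }))
  frac <- mean(mins$accel_available)
  se <- sqrt(0.8 * 0.2 / nrow(mins))
  expect_lt(abs(frac - 0.8), 3 * se)
})

test_that("response simulation follows the logistic model at its extremes", {
  roster <- one_profile()
  coefs_sat <- setNames(
    numeric(length(emawear:::model_term_names())),
    emawear:::model_term_names()
  )
  coefs_sat["intercept"] <- 20
  cfg <- deployment_config(response_model = coefs_sat)
  prompts <- apply_delivery(
    schedule_time_triggered(roster, 5), 0,
    seed = 2
  )
  out <- simulate_responses(prompts, roster, cfg, seed = 2)
  expect_true(all(out$answer_state %in% c("partial", "complete")))
  expect_true(all(abs(out$propensity - 1) < 1e-6))

  coefs_half <- coefs_sat
  coefs_half["intercept"] <- 0
  cfg2 <- deployment_config(response_model = coefs_half)
  prompts2 <- apply_delivery(
    schedule_time_triggered(roster, 60), 0,
    seed = 4
  )
  out2 <- simulate_responses(prompts2, roster, cfg2, seed = 4)
  answered <- mean(out2$answer_state != "not_answered")
  se <- sqrt(0.25 / nrow(out2))
  expect_lt(abs(answered - 0.5), 3 * se)
  expect_true(all(out2$propensity == 0.5))
})

test_that("simulate_deployment is deterministic given its seed", {
  cfg <- tiny_config()
  a <- simulate_deployment(cfg)
  b <- simulate_deployment(cfg)
  expect_identical(a$roster, b$roster)
  expect_identical(a$gestures, b$gestures)
  expect_identical(a$prompts, b$prompts)
  expect_identical(a$event_truth, b$event_truth)
})
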