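two_person_roster <- function() {
  tibble::tibble(
    participant_id = c("p1", "p2", "p3"),
    family_id = c("f1", "f1", "f2"),
    role = c("mother", "child", "father"),
    gender = c("female", "male", "male"),
    age_years = c(40, 14, 45),
    height_cm = c(165, 160, 178),
    window_start = hms::as_hms("07:00:00"),
    window_end = hms::as_hms("22:00:00")
  )
}

test_that("compliance rates reproduce hand-computed ratios", {
  prompts <- make_prompts(3723, 4171 - 3723)
  roster <- two_person_roster()
  r <- compliance_rates(prompts, roster, scope = "all", level = "overall")
  expect_identical(r$numerator, 3723L)
  expect_identical(r$denominator, 4171L)
  expect_equal(r$rate, 3723 / 4171, tolerance = 1e-12)

  zero <- compliance_rates(make_prompts(0, 25), roster,
    scope = "all",
    level = "overall"
  )
  expect_identical(zero$rate, 0)

  set.seed(31)
  flags <- runif(500) < 0.7
  mixed <- make_prompts(sum(flags), sum(!flags))
  r2 <- compliance_rates(mixed, roster, scope = "all", level = "overall")
  expect_equal(r2$rate, mean(flags), tolerance = 1e-12)

  expect_error(
    compliance_rates(make_prompts(5, 0), roster, scope = "event_triggered"),
    "undefined"
  )
})

test_that("family and individual levels report dispersion and conserve counts", {
  roster <- two_person_roster()
  prompts <- dplyr::bind_rows(
    make_prompts(8, 2, participant_id = "p1"),
    make_prompts(5, 5, participant_id = "p2"),
    make_prompts(9, 1, participant_id = "p3")
  )
  fam <- compliance_rates(prompts, roster, level = "family")
  ind <- compliance_rates(prompts, roster, level = "individual")
  ove <- compliance_rates(prompts, roster, level = "overall")

  expect_identical(ove$numerator, fam$numerator)
  expect_identical(ove$numerator, ind$numerator)
  expect_equal(ind$mean_rate, mean(c(0.8, 0.5, 0.9)), tolerance = 1e-12)
  expect_equal(ind$sd_rate, sd(c(0.8, 0.5, 0.9)), tolerance = 1e-12)
  expect_equal(fam$mean_rate, mean(c(13 / 20, 0.9)), tolerance = 1e-12)
  expect_identical(ind$n_units, 3L)

  # rates invariant to prompt ordering
  shuffled <- prompts[sample.int(nrow(prompts)), ]
  expect_equal(
    compliance_rates(shuffled, roster, level = "individual"),
    ind
  )
})

test_that("time-of-day bins split exactly at the stated boundaries", {
  roster <- two_person_roster()
  times <- c(
    "2024-03-04 00:00:00", "2024-03-04 11:59:59", "2024-03-04 12:00:00",
    "2024-03-04 16:59:59", "2024-03-04 17:00:00", "2024-03-04 23:59:59"
  )
  prompts <- make_prompts(6, 0, participant_id = "p1")
  prompts$sent_ts <- ts_at(times)
  prompts$received_ts <- ts_at(times)
  obs <- build_covariates(prompts, roster, "2024-03-04")
  expect_identical(
    obs$time_of_day_bin,
    c("morning", "morning", "afternoon", "afternoon", "evening", "evening")
  )
  expect_identical(obs$deployment_day, rep(1L, 6))
  # 2024-03-04 is a Monday; weekend flags Saturday/Sunday only
  expect_false(any(obs$weekend))
  sat <- prompts
  sat$received_ts <- sat$received_ts + 5 * 86400
  expect_true(all(build_covariates(sat, roster, "2024-03-04")$weekend))
  expect_identical(
    unique(build_covariates(sat, roster, "2024-03-04")$deployment_day), 6L
  )
})

test_that("the social covariate matches a brute-force all-pairs scan", {
  roster <- two_person_roster()
  set.seed(23)
  n <- 60
  mk <- function(pid) {
    p <- make_prompts(n, 0, participant_id = pid)
    t <- ts_at("2024-03-04 08:00:00") + sort(sample(0:50000, n))
    p$sent_ts <- t
    p$received_ts <- t
    p$answer_state <- ifelse(runif(n) < 0.6, "complete", "not_answered")
    p
  }
  prompts <- dplyr::bind_rows(mk("p1"), mk("p2"), mk("p3"))
  obs <- build_covariates(prompts, roster, "2024-03-04")

  fam <- setNames(roster$family_id, roster$participant_id)
  manual <- vapply(seq_len(nrow(prompts)), function(i) {
    any(
      fam[prompts$participant_id] == fam[[prompts$participant_id[i]]] &
        prompts$participant_id != prompts$participant_id[i] &
        abs(as.numeric(prompts$received_ts) -
          as.numeric(prompts$received_ts[i])) <= 900 &
        prompts$answer_state == "complete"
    )
  }, logical(1))
  expect_identical(obs$others_answered, manual)

  # a sole family member never has others_answered
  expect_false(any(obs$others_answered[obs$participant_id == "p3"]))

  expect_error(
    build_covariates(make_prompts(1, 0, participant_id = "ghost"), roster, "2024-03-04"),
    "ghost"
  )
})

test_that("a null generative model yields odds ratios near one", {
  coefs <- setNames(
    numeric(length(emawear:::model_term_names())),
    emawear:::model_term_names()
  )
  obs <- simulate_observations(20000, coefs, seed = 5)
  expect_equal(mean(obs$answered), 0.5, tolerance = 0.02)
  fit <- fit_compliance_model(obs, scope = "time_triggered")
  cf <- fit$coefficients
  expect_true(all(abs(cf$estimate[cf$term == "(Intercept)"]) < 0.15))
  expect_true(all(cf$odds_ratio[cf$term != "(Intercept)"] > 0.8))
  expect_true(all(cf$odds_ratio[cf$term != "(Intercept)"] < 1.25))
  expect_true(all(cf$ci_low <= cf$ci_high))
  expect_equal(cf$odds_ratio, exp(cf$estimate), tolerance = 1e-12)
})

test_that("the logistic fit matches direct Newton-Raphson maximization", {
  # a balanced outcome keeps the tiny-sample likelihood well conditioned
  coefs <- setNames(
    numeric(length(emawear:::model_term_names())),
    emawear:::model_term_names()
  )
  obs <- simulate_observations(120, coefs, seed = 9)
  fit <- suppressWarnings(fit_compliance_model(obs, scope = "time_triggered"))
  X <- cbind(
    1, obs$age_years, obs$time_of_day_bin == "afternoon",
    obs$time_of_day_bin == "evening", obs$weekend, obs$deployment_day,
    obs$female, obs$mother, obs$father, obs$others_answered
  )
  beta <- oracle_logistic_irls(X, obs$answered)
  expect_equal(unname(fit$coefficients$estimate), unname(beta),
    tolerance = 1e-6
  )
})

test_that("separation and degenerate scopes are reported, not returned", {
  coefs <- setNames(
    numeric(length(emawear:::model_term_names())),
    emawear:::model_term_names()
  )
  coefs["intercept"] <- 30
  all_yes <- simulate_observations(200, coefs, seed = 2)
  expect_error(fit_compliance_model(all_yes), "at least one answered")
})

test_that("dropping event prompts reproduces the time-triggered scope", {
  coefs <- reference_model_coefficients("all")
  obs <- simulate_observations(5000, coefs, seed = 13)
  tt_only <- obs[obs$prompt_type == "time_triggered", ]
  a <- fit_compliance_model(obs, scope = "time_triggered")
  b <- fit_compliance_model(tt_only, scope = "time_triggered")
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-12)
  expect_identical(a$n, b$n)
})
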