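# Compliance metrics and their logistic predictors. All functions operate
# on participation-filtered ("retained") prompts: prompts received at home.

is_answered <- function(answer_state) {
  !is.na(answer_state) & answer_state %in% c("partial", "complete")
}

scope_prompts <- function(prompts, scope) {
  switch(scope,
    all = prompts,
    time_triggered = prompts[prompts$prompt_type == "time_triggered", ],
    event_triggered = prompts[prompts$prompt_type == "event_triggered", ]
  )
}

#' Compliance rates
#'
#' Compliance is the fraction of retained (received-at-home) prompts that
#' were answered; a partially answered prompt counts as answered. At the
#' `overall` level a single pooled rate is returned; at the `family` and
#' `individual` levels the pooled numerator/denominator are accompanied by
#' the mean, SD, and range of per-unit rates. Units with zero retained
#' prompts in scope are flagged and excluded from the dispersion summary.
#'
#' @param prompts retained prompt tibble (after participation filtering).
#' @param roster roster tibble (supplies `family_id`).
#' @param scope which prompts to include: `"all"`, `"time_triggered"`, or
#'   `"event_triggered"`.
#' @param level `"overall"`, `"family"`, or `"individual"`.
#' @return one-row tibble with `level`, `prompt_scope`, `numerator`,
#'   `denominator`, `rate`, and (for family/individual levels)
#'   `mean_rate`, `sd_rate`, `min_rate`, `max_rate`, `n_units`,
#'   `n_undefined`.
#' @export
compliance_rates <- function(prompts, roster,
                             scope = c("all", "time_triggered", "event_triggered"),
                             level = c("overall", "family", "individual")) {
  scope <- match.arg(scope)
  level <- match.arg(level)
  prompts <- scope_prompts(prompts, scope)
  num <- sum(is_answered(prompts$answer_state))
  den <- nrow(prompts)
  if (den == 0) {
    stop("no retained prompts in scope '", scope, "'; rate undefined",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    level = level, prompt_scope = scope,
    numerator = num, denominator = den, rate = num / den
  )
  if (level == "overall") {
    return(out)
  }
  unit_col <- if (level == "family") "family_id" else "participant_id"
  prompts <- dplyr::left_join(
    prompts,
    roster[, c("participant_id", "family_id")],
    by = "participant_id"
  )
  units <- prompts |>
    dplyr::group_by(unit = .data[[unit_col]]) |>
    dplyr::summarise(
      num = sum(is_answered(.data$answer_state)),
      den = dplyr::n(), .groups = "drop"
    )
  # units absent from the prompt table have zero denominator: undefined
  all_units <- unique(roster[[unit_col]])
  n_undefined <- sum(!all_units %in% units$unit)
  rates <- units$num / units$den
  dplyr::mutate(out,
    mean_rate = mean(rates), sd_rate = stats::sd(rates),
    min_rate = min(rates), max_rate = max(rates),
    n_units = nrow(units), n_undefined = n_undefined
  )
}

#' Build model covariates for retained prompts
#'
#' One observation per retained prompt, with the covariates of the
#' compliance models: time-of-day bin from `received_ts` local time
#' (morning = midnight-11:59:59, afternoon = noon-16:59:59, evening =
#' 17:00:00-23:59:59), weekend (Saturday/Sunday), deployment day (1 + whole
#' days since the family's deployment start), age, gender, family-role
#' contrasts (mother, father; children and any other role form the
#' reference), and the social covariate `others_answered`: whether any
#' other member of the same family answered a retained prompt received
#' within +/-15 minutes of the focal prompt's `received_ts`.
#'
#' @param prompts retained prompt tibble.
#' @param roster roster tibble.
#' @param deployment_start first deployment day (Date or string); shared by
#'   all members of a family.
#' @param social_window_minutes half-width of the social window.
#' @return tibble of observations, one per retained prompt, including the
#'   0/1 `answered` outcome.
#' @export
build_covariates <- function(prompts, roster, deployment_start,
                             social_window_minutes = 15) {
  missing_ids <- setdiff(prompts$participant_id, roster$participant_id)
  if (length(missing_ids) > 0) {
    stop(
      "prompts reference participants absent from roster: ",
      paste(utils::head(missing_ids, 5), collapse = ", "),
      call. = FALSE
    )
  }
  obs <- dplyr::left_join(
    prompts,
    roster[, c("participant_id", "family_id", "role", "gender", "age_years")],
    by = "participant_id"
  )
  secs <- clock_seconds(obs$received_ts)
  start_num <- as.numeric(as.POSIXct(as.Date(deployment_start), tz = .tz))
  answered <- as.integer(is_answered(obs$answer_state))

  rec <- as.numeric(obs$received_ts)
  win <- social_window_minutes * 60
  others <- vapply(seq_len(nrow(obs)), function(i) {
    any(
      obs$family_id == obs$family_id[i] &
        obs$participant_id != obs$participant_id[i] &
        abs(rec - rec[i]) <= win &
        answered == 1L
    )
  }, logical(1))

  tibble::tibble(
    prompt_id = obs$prompt_id,
    participant_id = obs$participant_id,
    family_id = obs$family_id,
    answered = answered,
    prompt_type = obs$prompt_type,
    time_of_day_bin = dplyr::case_when(
      secs < 12 * 3600 ~ "morning",
      secs < 17 * 3600 ~ "afternoon",
      TRUE ~ "evening"
    ),
    weekend = lubridate::wday(obs$received_ts, week_start = 1) >= 6,
    deployment_day = as.integer(1 + floor((rec - start_num) / 86400)),
    age_years = obs$age_years,
    female = obs$gender == "female",
    mother = obs$role == "mother",
    father = obs$role == "father",
    others_answered = others
  )
}

#' Fit a compliance model
#'
#' Maximum-likelihood logistic regression of the 0/1 answered outcome on
#' age, afternoon, evening, weekend, deployment day, female, mother,
#' father, and others-answered; the pooled (`"all"`) scope additionally
#' includes an event-triggered prompt-type indicator. Observations are
#' treated as independent. Wald 95% confidence intervals are formed on the
#' log-odds scale and exponentiated.
#'
#' @param observations tibble from [build_covariates()].
#' @param scope `"all"`, `"time_triggered"`, or `"event_triggered"`;
#'   non-pooled scopes subset on `prompt_type`.
#' @param conf_level confidence level for the Wald intervals.
#' @return list of class `"compliance_model"` with elements `scope`,
#'   `coefficients` (tibble: term, estimate, std_error, odds_ratio,
#'   ci_low, ci_high), `n`, `converged`, `aic`, `bic`, and the underlying
#'   `fit`.
#' @export
fit_compliance_model <- function(observations,
                                 scope = c("all", "time_triggered", "event_triggered"),
                                 conf_level = 0.95) {
  scope <- match.arg(scope)
  obs <- if (scope == "all") {
    observations
  } else {
    observations[observations$prompt_type == scope, ]
  }
  if (sum(obs$answered) == 0 || sum(obs$answered) == nrow(obs)) {
    stop("scope '", scope, "' needs at least one answered and one unanswered ",
      "observation",
      call. = FALSE
    )
  }
  dat <- data.frame(
    answered = obs$answered,
    age_years = obs$age_years,
    afternoon = as.integer(obs$time_of_day_bin == "afternoon"),
    evening = as.integer(obs$time_of_day_bin == "evening"),
    weekend = as.integer(obs$weekend),
    deployment_day = obs$deployment_day,
    female = as.integer(obs$female),
    mother = as.integer(obs$mother),
    father = as.integer(obs$father),
    others_answered = as.integer(obs$others_answered)
  )
  form <- answered ~ age_years + afternoon + evening + weekend +
    deployment_day + female + mother + father + others_answered
  if (scope == "all") {
    dat$event_triggered <- as.integer(obs$prompt_type == "event_triggered")
    form <- stats::update(form, . ~ . + event_triggered)
  }
  fit <- glm(form, family = binomial(), data = dat)
  if (!fit$converged) {
    stop("logistic fit for scope '", scope, "' did not converge", call. = FALSE)
  }
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  if (any(se > 1e3)) {
    warning("very large standard errors suggest (quasi-)separation in scope '",
      scope, "'",
      call. = FALSE
    )
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    scope = scope,
    coefficients = tibble::tibble(
      term = names(beta),
      estimate = unname(beta),
      std_error = unname(se),
      odds_ratio = exp(unname(beta)),
      ci_low = exp(unname(beta - z * se)),
      ci_high = exp(unname(beta + z * se))
    ),
    n = nrow(dat),
    converged = fit$converged,
    aic = AIC(fit),
    bic = BIC(fit),
    fit = fit
  ), class = "compliance_model")
}

#' @export
print.compliance_model <- function(x, ...) {
  cat(sprintf(
    "<compliance_model scope=%s n=%d AIC=%.2f>\n", x$scope, x$n, x$aic
  ))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Simulate prompt-level observations from a coefficient set
#'
#' Draws covariates mimicking the mix seen in a two-week in-home family
#' deployment — time-of-day split 18.6/30.5/51.0% morning/afternoon/
#' evening, 2/7 weekend, deployment day uniform on 1-14, roles 57.5%
#' child / 31.8% mother / 10.7% father, child ages 11-18 and parent ages
#' around 44, and a configurable others-answered prevalence — then draws
#' the 0/1 answered outcome from the logistic model with the supplied
#' log-odds coefficients. Used for simulation-based parameter-recovery
#' experiments: refitting [fit_compliance_model()] on the output should
#' recover `coefficients`.
#'
#' @param n number of observations.
#' @param coefficients named log-odds vector, see
#'   [reference_model_coefficients()].
#' @param prompt_type prompt type recorded on every observation; when
#'   `coefficients` carries an `event_triggered` term, types are instead
#'   mixed 89/11% time/event-triggered.
#' @param others_prob prevalence of the others-answered covariate.
#' @param deployment_days range of the deployment-day covariate.
#' @param seed optional integer seed.
#' @return an observation tibble suitable for [fit_compliance_model()].
#' @export
simulate_observations <- function(n, coefficients,
                                  prompt_type = "time_triggered",
                                  others_prob = 0.5,
                                  deployment_days = 14,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tod <- sample(c("morning", "afternoon", "evening"), n,
    replace = TRUE, prob = c(0.186, 0.305, 0.510)
  )
  weekend <- runif(n) < 2 / 7
  day <- sample.int(deployment_days, n, replace = TRUE)
  role <- sample(c("child", "mother", "father"), n,
    replace = TRUE, prob = c(0.575, 0.318, 0.107)
  )
  female <- ifelse(role == "mother", TRUE,
    ifelse(role == "father", FALSE, runif(n) < 0.4)
  )
  age <- ifelse(role == "child",
    sample(11:18, n, replace = TRUE),
    pmin(pmax(round(rnorm(n, 43.7, 6.7), 1), 25), 70)
  )
  others <- runif(n) < others_prob
  has_type <- "event_triggered" %in% names(coefficients)
  type <- if (has_type) {
    sample(c("time_triggered", "event_triggered"), n,
      replace = TRUE, prob = c(0.89, 0.11)
    )
  } else {
    rep(prompt_type, n)
  }
  eta <- coefficients[["intercept"]] +
    coefficients[["age_years"]] * age +
    coefficients[["afternoon"]] * (tod == "afternoon") +
    coefficients[["evening"]] * (tod == "evening") +
    coefficients[["weekend"]] * weekend +
    coefficients[["deployment_day"]] * day +
    coefficients[["female"]] * female +
    coefficients[["mother"]] * (role == "mother") +
    coefficients[["father"]] * (role == "father") +
    coefficients[["others_answered"]] * others +
    (if (has_type) {
      coefficients[["event_triggered"]] * (type == "event_triggered")
    } else {
      0
    })
  tibble::tibble(
    prompt_id = sprintf("S%07d", seq_len(n)),
    participant_id = "sim",
    family_id = "sim",
    answered = as.integer(runif(n) < plogis(eta)),
    prompt_type = type,
    time_of_day_bin = tod,
    weekend = weekend,
    deployment_day = day,
    age_years = age,
    female = female,
    mother = role == "mother",
    father = role == "father",
    others_answered = others
  )
}

#' Odds-ratio recovery by simulation and refit
#'
#' For each replicate seed, simulates `n` observations from the supplied
#' coefficient set via [simulate_observations()], refits the matching
#' logistic model, and returns the exponentiated coefficients. The
#' replicate mean is the Monte-Carlo estimate of each recovered odds
#' ratio.
#'
#' @param coefficients named log-odds vector.
#' @param n observations per replicate.
#' @param seeds integer vector of replicate seeds.
#' @param scope model scope passed to [fit_compliance_model()].
#' @inheritParams simulate_observations
#' @return tibble with one row per (replicate, term): `seed`, `term`,
#'   `odds_ratio`.
#' @export
recover_odds_ratios <- function(coefficients, n = 50000,
                                seeds = 1:20,
                                scope = "time_triggered",
                                others_prob = 0.5) {
  purrr::map_dfr(seeds, function(s) {
    obs <- simulate_observations(n, coefficients,
      prompt_type = if (scope == "all") "time_triggered" else scope,
      others_prob = others_prob, seed = s
    )
    fit <- fit_compliance_model(obs, scope = scope)
    tibble::tibble(
      seed = s,
      term = fit$coefficients$term,
      odds_ratio = fit$coefficients$odds_ratio
    )
  })
}
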