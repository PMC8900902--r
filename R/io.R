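# Table I/O and the pipeline driver. All tables travel as RFC 4180 CSV
# with a header row; timestamps are ISO-8601 naive local time
# ("%Y-%m-%dT%H:%M:%S"); the prompt table's item responses are serialized
# as a JSON string column.

.ts_fmt <- "%Y-%m-%dT%H:%M:%S"

ema_schemas <- function() {
  list(
    roster = list(
      participant_id = "chr", family_id = "chr", role = "chr",
      gender = "chr", age_years = "dbl", height_cm = "dbl",
      window_start = "clock", window_end = "clock"
    ),
    gestures = list(
      participant_id = "chr", timestamp = "ts", source = "chr",
      bout_id = "chr"
    ),
    bouts = list(
      bout_id = "chr", participant_id = "chr", start_ts = "ts",
      end_ts = "ts", n_gestures = "int"
    ),
    sensor_minutes = list(
      participant_id = "chr", minute_start = "ts", accel_available = "lgl",
      movement = "lgl", beacon_available = "lgl"
    ),
    events = list(
      event_id = "chr", participant_id = "chr", start_ts = "ts",
      end_ts = "ts", gesture_count = "int"
    ),
    prompts = list(
      prompt_id = "chr", participant_id = "chr", prompt_type = "chr",
      linked_event_id = "chr", sent_ts = "ts", received = "lgl",
      received_ts = "ts", answer_state = "chr",
      first_question_eating = "chr", responses = "json"
    ),
    intervals = list(
      participant_id = "chr", start_ts = "ts", end_ts = "ts"
    ),
    observations = list(
      prompt_id = "chr", participant_id = "chr", family_id = "chr",
      answered = "int", prompt_type = "chr", time_of_day_bin = "chr",
      weekend = "lgl", deployment_day = "int", age_years = "dbl",
      female = "lgl", mother = "lgl", father = "lgl",
      others_answered = "lgl"
    )
  )
}

#' Write a pipeline table as CSV
#'
#' @param x tibble matching the schema.
#' @param path output file path.
#' @param schema_id one of `names(ema_schemas())`:
#'   roster, gestures, bouts, sensor_minutes, events, prompts, intervals,
#'   observations.
#' @return `path`, invisibly.
#' @export
write_ema_table <- function(x, path, schema_id) {
  schema <- ema_schemas()[[schema_id]]
  if (is.null(schema)) stop("unknown schema_id '", schema_id, "'", call. = FALSE)
  validate_ema_table(x, schema_id)
  out <- x[, names(schema)]
  for (col in names(schema)) {
    out[[col]] <- switch(schema[[col]],
      ts = format(out[[col]], .ts_fmt),
      clock = format(out[[col]]),
      json = vapply(out[[col]], function(r) {
        if (is.null(r)) "" else as.character(jsonlite::toJSON(r, auto_unbox = TRUE))
      }, character(1)),
      out[[col]]
    )
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a pipeline table from CSV
#'
#' Rows are schema-validated after parsing; malformed rows are reported
#' with their line numbers.
#'
#' @inheritParams write_ema_table
#' @return a validated tibble.
#' @export
read_ema_table <- function(path, schema_id) {
  schema <- ema_schemas()[[schema_id]]
  if (is.null(schema)) stop("unknown schema_id '", schema_id, "'", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- lapply(schema, function(tp) {
    switch(tp,
      chr = readr::col_character(),
      dbl = readr::col_double(),
      int = readr::col_integer(),
      lgl = readr::col_logical(),
      ts = readr::col_character(),
      clock = readr::col_character(),
      json = readr::col_character()
    )
  })
  x <- readr::read_csv(path,
    col_types = do.call(readr::cols, cols), na = "",
    progress = FALSE
  )
  missing_cols <- setdiff(names(schema), names(x))
  if (length(missing_cols) > 0) {
    stop("table is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in names(schema)) {
    x[[col]] <- switch(schema[[col]],
      ts = {
        parsed <- as.POSIXct(x[[col]], format = .ts_fmt, tz = .tz)
        bad <- which(!is.na(x[[col]]) & is.na(parsed))
        if (length(bad) > 0) {
          stop("unparseable timestamp in '", col, "' at data row(s) ",
            paste(utils::head(bad, 5), collapse = ", "),
            call. = FALSE
          )
        }
        parsed
      },
      clock = as_clock(x[[col]]),
      json = lapply(x[[col]], function(s) {
        if (is.na(s) || s == "") NULL else jsonlite::fromJSON(s, simplifyVector = TRUE)
      }),
      x[[col]]
    )
  }
  validate_ema_table(x, schema_id)
  x
}

#' Validate a pipeline table against its schema invariants
#'
#' Beyond column presence, enforces the record-level invariants:
#' prompts must have `received_ts` iff `received` and may only be answered
#' if received, `first_question_eating` only on event-triggered prompts;
#' sensor minutes must be minute-aligned and unique per participant;
#' intervals must have `start_ts < end_ts`. Violations are reported with
#' row numbers.
#'
#' @param x the table.
#' @param schema_id schema name.
#' @return `x`, invisibly, or an error naming the offending field and rows.
#' @export
validate_ema_table <- function(x, schema_id) {
  schema <- ema_schemas()[[schema_id]]
  missing_cols <- setdiff(names(schema), names(x))
  if (length(missing_cols) > 0) {
    stop("table is missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_rows <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) {
      stop(msg, " at row(s) ", paste(utils::head(idx, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (schema_id == "prompts") {
    resolved <- !is.na(x$received)
    bad_rows(
      resolved & x$received & is.na(x$received_ts),
      "received=TRUE but missing received_ts"
    )
    bad_rows(
      resolved & !x$received & !is.na(x$received_ts),
      "received=FALSE but received_ts present"
    )
    bad_rows(
      !is.na(x$answer_state) & x$answer_state != "not_answered" &
        resolved & !x$received,
      "answered prompt marked not received"
    )
    bad_rows(
      !is.na(x$first_question_eating) & x$prompt_type != "event_triggered",
      "first_question_eating on a non-event prompt"
    )
  }
  if (schema_id == "sensor_minutes") {
    bad_rows(
      as.numeric(x$minute_start) %% 60 != 0,
      "minute_start not aligned to :00 seconds"
    )
    bad_rows(
      duplicated(x[, c("participant_id", "minute_start")]),
      "duplicate (participant, minute) record"
    )
  }
  if (schema_id %in% c("intervals", "bouts", "events")) {
    s <- if ("start_ts" %in% names(x)) x$start_ts else NULL
    e <- if ("end_ts" %in% names(x)) x$end_ts else NULL
    if (!is.null(s)) {
      cmp <- if (schema_id == "intervals") s >= e else s > e
      bad_rows(cmp, "start_ts after end_ts")
    }
  }
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes simulate, detect, schedule/deliver, participation-filter,
#' compliance, and validity in sequence, optionally writing every
#' intermediate table, a human-readable report, and a run manifest under
#' `outdir`. Identical configurations produce byte-identical outputs.
#'
#' @param config a [deployment_config()].
#' @param outdir optional output directory; created if needed.
#' @return list with the simulated `deployment`, `participation` (interval
#'   sets and retained prompts), `observations`, `compliance` (rate table),
#'   `models` (per scope, or the failure message), `validity` (outcomes,
#'   per-person summaries, dispersion, subgroup tests), and `manifest`.
#' @export
run_pipeline <- function(config = deployment_config(), outdir = NULL) {
  stage <- "simulate"
  result <- tryCatch(
    {
      dep <- simulate_deployment(config)

      stage <- "participation"
      part <- participation_algorithm(
        dep$prompts, dep$sensor_minutes,
        radius_minutes = config$anchor_radius_minutes
      )
      retained <- part$retained_prompts

      stage <- "compliance"
      obs <- build_covariates(retained, dep$roster, config$start_date)
      rates <- dplyr::bind_rows(lapply(
        c("all", "time_triggered", "event_triggered"),
        function(sc) {
          dplyr::bind_rows(lapply(
            c("overall", "family", "individual"),
            function(lv) {
              tryCatch(
                compliance_rates(retained, dep$roster, scope = sc, level = lv),
                error = function(e) NULL
              )
            }
          ))
        }
      ))
      models <- lapply(
        stats::setNames(
          nm = c("all", "time_triggered", "event_triggered")
        ),
        function(sc) {
          # small deployments routinely quasi-separate; convergence and SE
          # diagnostics live in the returned object
          tryCatch(suppressWarnings(fit_compliance_model(obs, scope = sc)),
            error = function(e) conditionMessage(e)
          )
        }
      )

      stage <- "validity"
      event_prompts <- retained[retained$prompt_type == "event_triggered", ]
      validity <- if (nrow(event_prompts) > 0) {
        outcomes <- label_detections(event_prompts)
        summaries <- per_person_proportions(outcomes)
        list(
          outcomes = outcomes,
          summaries = summaries,
          dispersion = tryCatch(proportion_summary(summaries),
            error = function(e) conditionMessage(e)
          ),
          precision = tryCatch(detection_precision(outcomes),
            error = function(e) NA_real_
          ),
          tests = tryCatch(subgroup_tests(summaries, dep$roster),
            error = function(e) conditionMessage(e)
          )
        )
      } else {
        list(
          outcomes = NULL, summaries = NULL, dispersion = NULL,
          precision = NA_real_, tests = NULL
        )
      }

      list(
        deployment = dep, participation = part, observations = obs,
        compliance = rates, models = models, validity = validity
      )
    },
    error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    }
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("emawear")),
    seed = config$random_seed,
    config_hash = rlang::hash(unclass(config)),
    row_counts = list(
      roster = nrow(result$deployment$roster),
      gestures = nrow(result$deployment$gestures),
      bouts = nrow(result$deployment$bouts),
      sensor_minutes = nrow(result$deployment$sensor_minutes),
      events = nrow(result$deployment$events),
      prompts_sent = nrow(result$deployment$prompts),
      prompts_received = sum(result$deployment$prompts$received),
      prompts_retained = nrow(result$participation$retained_prompts)
    )
  )
  result$manifest <- manifest

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wp <- function(x, name, schema) {
      write_ema_table(x, file.path(outdir, paste0(name, ".csv")), schema)
    }
    wp(result$deployment$roster, "roster", "roster")
    wp(result$deployment$gestures, "gestures", "gestures")
    wp(result$deployment$bouts, "bouts", "bouts")
    wp(result$deployment$sensor_minutes, "sensor_minutes", "sensor_minutes")
    wp(result$deployment$events, "events", "events")
    wp(result$deployment$prompts, "prompts", "prompts")
    wp(result$participation$intervals, "participation_intervals", "intervals")
    wp(result$observations, "observations", "observations")
    readr::write_csv(result$compliance, file.path(outdir, "compliance_rates.csv"))
    jsonlite::write_json(
      manifest, file.path(outdir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
    writeLines(pipeline_report(result), file.path(outdir, "report.txt"))
  }
  result
}

#' Human-readable pipeline report
#'
#' @param result the list returned by [run_pipeline()].
#' @return character vector of report lines.
#' @export
pipeline_report <- function(result) {
  rc <- result$manifest$row_counts
  lines <- c(
    "== deployment ==",
    sprintf(
      "participants %d, gestures %d, true bouts %d, detected at-home events %d",
      rc$roster, rc$gestures, rc$bouts, rc$events
    ),
    sprintf(
      "prompts sent %d, received %d, retained after participation %d (%.2f%% of received)",
      rc$prompts_sent, rc$prompts_received, rc$prompts_retained,
      100 * rc$prompts_retained / max(rc$prompts_received, 1)
    ),
    "", "== compliance =="
  )
  comp <- result$compliance
  for (i in seq_len(nrow(comp))) {
    lines <- c(lines, sprintf(
      "%s / %s: %d/%d = %.2f%%%s",
      comp$prompt_scope[i], comp$level[i], comp$numerator[i],
      comp$denominator[i], 100 * comp$rate[i],
      if (!is.na(comp$mean_rate[i] %||% NA)) {
        sprintf(
          " (unit mean %.1f%%, SD %.1f%%, range %.1f-%.1f%%)",
          100 * comp$mean_rate[i], 100 * comp$sd_rate[i],
          100 * comp$min_rate[i], 100 * comp$max_rate[i]
        )
      } else {
        ""
      }
    ))
  }
  lines <- c(lines, "", "== models ==")
  for (sc in names(result$models)) {
    m <- result$models[[sc]]
    if (is.character(m)) {
      lines <- c(lines, sprintf("%s: not fitted (%s)", sc, m))
    } else {
      lines <- c(lines, sprintf("%s (n=%d, AIC=%.2f):", sc, m$n, m$aic))
      cf <- m$coefficients
      lines <- c(lines, sprintf(
        "  %-16s beta %6.3f (SE %.3f)  OR %.2f (%.2f-%.2f)",
        cf$term, cf$estimate, cf$std_error, cf$odds_ratio, cf$ci_low,
        cf$ci_high
      ))
    }
  }
  v <- result$validity
  lines <- c(lines, "", "== validity ==")
  if (!is.null(v$outcomes)) {
    lines <- c(lines, sprintf(
      "event prompts %d: TP %d, FP %d, unverified %d; precision %.4f",
      nrow(v$outcomes), sum(v$outcomes$label == "true_positive"),
      sum(v$outcomes$label == "false_positive"),
      sum(v$outcomes$label == "unverified"), v$precision
    ))
    if (is.data.frame(v$dispersion)) {
      lines <- c(lines, sprintf(
        "per-person correct proportion (n=%d included): mean %.3f, SD %.3f, range %.3f-%.3f",
        v$dispersion$n, v$dispersion$mean, v$dispersion$sd,
        v$dispersion$min, v$dispersion$max
      ))
    }
  } else {
    lines <- c(lines, "no event-triggered prompts retained")
  }
  lines
}

`%||%` <- function(a, b) if (is.null(a)) b else a
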