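# Detection-validity metrics. The design can only verify detections that
# triggered a confirmation prompt whose first question was answered, so
# true/false positives are observable and negatives never are; precision
# is the validity metric, and no recall/F1/accuracy is ever emitted.

#' Label detections from their confirmation prompts
#'
#' Event-triggered prompts carry the ground-truth answer to "Were you
#' eating or drinking just now?". A yes makes the linked detection a true
#' positive (drink-only confirmations count: the question covers eating or
#' drinking); a no makes it a false positive, with the reported activity
#' captured when present; a missing first question leaves the detection
#' unverified and excluded from validity analyses.
#'
#' @param event_prompts prompt tibble containing only event-triggered
#'   prompts (an error otherwise) that were received.
#' @return tibble `event_id`, `participant_id`, `prompt_id`, `label`
#'   (`true_positive`/`false_positive`/`unverified`), `reported_activity`.
#' @export
label_detections <- function(event_prompts) {
  if (any(event_prompts$prompt_type != "event_triggered")) {
    stop("label_detections() expects event-triggered prompts only",
      call. = FALSE
    )
  }
  activity <- vapply(seq_len(nrow(event_prompts)), function(i) {
    r <- event_prompts$responses[[i]]
    if (is.list(r) && !is.null(r$activity)) as.character(r$activity) else NA_character_
  }, character(1))
  fq <- event_prompts$first_question_eating
  tibble::tibble(
    event_id = event_prompts$linked_event_id,
    participant_id = event_prompts$participant_id,
    prompt_id = event_prompts$prompt_id,
    label = dplyr::case_when(
      is.na(fq) ~ "unverified",
      fq == "yes" ~ "true_positive",
      TRUE ~ "false_positive"
    ),
    reported_activity = ifelse(is.na(fq) | fq == "yes", NA_character_, activity)
  )
}

#' Precision of the eating-event detector
#'
#' Precision = true positives / (true positives + false positives), over
#' verified detections only; unverified detections (first question
#' unanswered) are excluded from both numerator and denominator.
#'
#' @param outcomes tibble from [label_detections()].
#' @return precision in `[0, 1]`.
#' @export
#' @examples
#' outcomes <- tibble::tibble(label = rep(c("true_positive", "false_positive"),
#'   c(302, 93)
#' ))
#' detection_precision(outcomes) # 302/395
detection_precision <- function(outcomes) {
  tp <- sum(outcomes$label == "true_positive")
  fp <- sum(outcomes$label == "false_positive")
  if (tp + fp == 0) {
    stop("no verified detections; precision undefined", call. = FALSE)
  }
  tp / (tp + fp)
}

#' Per-participant proportion of correctly detected events
#'
#' For each participant, the proportion of verified detections that were
#' confirmed eating events (true positives / (true positives + false
#' positives)). Participants who received fewer than `min_prompts`
#' event-triggered prompts are flagged `included = FALSE` and excluded
#' from group comparisons.
#'
#' @param outcomes tibble from [label_detections()]; one row per received
#'   event prompt.
#' @param min_prompts minimum received event prompts for inclusion
#'   (default 3).
#' @return tibble `participant_id`, `n_prompts`, `tp`, `fp`, `n_verified`,
#'   `proportion_correct`, `included`.
#' @export
per_person_proportions <- function(outcomes, min_prompts = 3) {
  outcomes |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_prompts = dplyr::n(),
      tp = sum(.data$label == "true_positive"),
      fp = sum(.data$label == "false_positive"),
      n_verified = .data$tp + .data$fp,
      proportion_correct = ifelse(.data$n_verified > 0,
        .data$tp / .data$n_verified, NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(included = .data$n_prompts >= min_prompts)
}

#' Dispersion summary of included per-person proportions
#'
#' @param summaries tibble from [per_person_proportions()].
#' @return one-row tibble with `n`, `mean`, `sd`, `min`, `max` over
#'   included participants with a defined proportion.
#' @export
proportion_summary <- function(summaries) {
  p <- summaries$proportion_correct[summaries$included &
    !is.na(summaries$proportion_correct)]
  tibble::tibble(
    n = length(p), mean = mean(p), sd = stats::sd(p),
    min = min(p), max = max(p)
  )
}

#' Subgroup tests of detection proportions
#'
#' Nonparametric comparisons of the per-person proportion of correctly
#' detected events across demographic groups, on included participants
#' only: gender by two-sided Mann-Whitney U, family role
#' (child/father/mother) by Kruskal-Wallis, and age and height by Spearman
#' rank correlation. Ties are handled by midranks with the usual normal /
#' chi-square approximations; groups with fewer than 2 members are
#' flagged.
#'
#' @param summaries tibble from [per_person_proportions()].
#' @param roster roster tibble (supplies gender, role, age, height).
#' @return list of class `"subgroup_tests"` with elements `gender`,
#'   `role`, `age`, `height`, each a list of statistic, p-value, and group
#'   sizes (plus `flags` for undersized groups).
#' @export
subgroup_tests <- function(summaries, roster) {
  dat <- summaries[summaries$included & !is.na(summaries$proportion_correct), ] |>
    dplyr::left_join(
      roster[, c("participant_id", "gender", "role", "age_years", "height_cm")],
      by = "participant_id"
    )
  flags <- character()

  g_sizes <- table(dat$gender)
  if (any(g_sizes < 2) || length(g_sizes) < 2) {
    flags <- c(flags, "gender: a group has fewer than 2 members")
  }
  gender <- tryCatch(
    {
      gw <- suppressWarnings(wilcox.test(
        proportion_correct ~ gender,
        data = dat, exact = FALSE, correct = FALSE
      ))
      list(
        statistic = unname(gw$statistic), p_value = gw$p.value,
        n = as.list(g_sizes)
      )
    },
    error = function(e) {
      flags <<- c(flags, paste0("gender: ", conditionMessage(e)))
      NULL
    }
  )

  r_sizes <- table(dat$role)
  if (any(r_sizes < 2)) {
    flags <- c(flags, "role: a group has fewer than 2 members")
  }
  role <- tryCatch(
    {
      kw <- kruskal.test(proportion_correct ~ factor(role), data = dat)
      list(
        statistic = unname(kw$statistic), df = unname(kw$parameter),
        p_value = kw$p.value, n = as.list(r_sizes)
      )
    },
    error = function(e) {
      flags <<- c(flags, paste0("role: ", conditionMessage(e)))
      NULL
    }
  )

  sp <- function(x) {
    tryCatch(
      {
        ct <- suppressWarnings(
          cor.test(x, dat$proportion_correct, method = "spearman", exact = FALSE)
        )
        list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(dat))
      },
      error = function(e) {
        flags <<- c(flags, paste0("correlation: ", conditionMessage(e)))
        NULL
      }
    )
  }

  structure(
    list(
      gender = gender, role = role,
      age = sp(dat$age_years), height = sp(dat$height_cm),
      flags = flags
    ),
    class = "subgroup_tests"
  )
}

#' @export
print.subgroup_tests <- function(x, ...) {
  cat("<subgroup_tests>\n")
  if (!is.null(x$gender)) {
    cat(sprintf(
      "  gender  Mann-Whitney U = %.1f, p = %.3f\n",
      x$gender$statistic, x$gender$p_value
    ))
  }
  if (!is.null(x$role)) {
    cat(sprintf(
      "  role    Kruskal-Wallis chi2(%d) = %.3f, p = %.3f\n",
      x$role$df, x$role$statistic, x$role$p_value
    ))
  }
  if (!is.null(x$age)) {
    cat(sprintf(
      "  age     Spearman rho = %.3f, p = %.3f\n", x$age$rho, x$age$p_value
    ))
  }
  if (!is.null(x$height)) {
    cat(sprintf(
      "  height  Spearman rho = %.3f, p = %.3f\n",
      x$height$rho, x$height$p_value
    ))
  }
  for (f in x$flags) cat("  flag:", f, "\n")
  invisible(x)
}
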