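# Session-log data model and delimited-text I/O.
#
# A cohort is four tidy tables:
#   sessions       one row per (participant, condition) session attempt
#   trials         one row per encoding-item / recall-response pair
#   motion         one row per 100 Hz foot-motion-pad sample
#   questionnaires one row per questionnaire item response
#
# On disk each table is a comma-separated UTF-8 file with a '.' decimal
# separator, a header row, and a leading versioned comment line
# ("# navassess-log v1"). See `cohort_schema()` for the column contract.

LOG_FORMAT_HEADER <- "# navassess-log v1"

#' Column schema of the session-log format
#'
#' Returns the expected file names and column layouts of the on-disk cohort
#' format. Coordinates (`enc_x`, `enc_z`, `rec_x`, `rec_z`) live on the
#' horizontal plane of the virtual environment, in virtual units; the
#' vertical axis never appears in position logs. `pitch_y` and `yaw_z` are
#' dimensionless normalized pad tilts in \[-1, 1\] (toe–heel and left–right
#' respectively); `t_ms` is milliseconds since phase start with a nominal
#' 10 ms spacing (100 Hz).
#'
#' @return a named list of character vectors (column names per file).
#' @export
cohort_schema <- function() {
  list(
    sessions = c("participant_id", "condition", "completed",
                 "encoding_duration", "recall_duration"),
    trials = c("participant_id", "condition", "landmark", "item_id",
               "repetition", "enc_x", "enc_z", "rec_x", "rec_z",
               "recall_latency"),
    motion = c("participant_id", "condition", "phase", "t_ms",
               "pitch_y", "yaw_z"),
    questionnaires = c("participant_id", "condition", "instrument",
                       "item", "response")
  )
}

cohort_col_types <- function() {
  list(
    sessions = readr::cols(
      participant_id = readr::col_character(),
      condition = readr::col_character(),
      completed = readr::col_logical(),
      encoding_duration = readr::col_double(),
      recall_duration = readr::col_double()
    ),
    trials = readr::cols(
      participant_id = readr::col_character(),
      condition = readr::col_character(),
      landmark = readr::col_character(),
      item_id = readr::col_integer(),
      repetition = readr::col_integer(),
      enc_x = readr::col_double(),
      enc_z = readr::col_double(),
      rec_x = readr::col_double(),
      rec_z = readr::col_double(),
      recall_latency = readr::col_double()
    ),
    motion = readr::cols(
      participant_id = readr::col_character(),
      condition = readr::col_character(),
      phase = readr::col_character(),
      t_ms = readr::col_integer(),
      pitch_y = readr::col_double(),
      yaw_z = readr::col_double()
    ),
    questionnaires = readr::cols(
      participant_id = readr::col_character(),
      condition = readr::col_character(),
      instrument = readr::col_character(),
      item = readr::col_integer(),
      response = readr::col_integer()
    )
  )
}

empty_cohort_table <- function(which) {
  types <- cohort_col_types()[[which]]$cols
  cols <- lapply(types, function(ct) {
    switch(class(ct)[1],
           collector_character = character(0),
           collector_logical = logical(0),
           collector_integer = integer(0),
           collector_double = double(0))
  })
  tibble::as_tibble(cols)
}

#' Construct a cohort object
#'
#' Bundles the four session-log tables into a `nav_cohort`. Columns are
#' checked for presence; deeper invariants (trial counts, timestamp
#' monotonicity, ...) are the business of [validate_sessions()].
#'
#' @param sessions,trials,motion,questionnaires data frames following
#'   [cohort_schema()]. Missing tables default to empty.
#' @return an object of class `nav_cohort`: a named list of four tibbles.
#' @export
nav_cohort <- function(sessions = NULL, trials = NULL, motion = NULL,
                       questionnaires = NULL) {
  schema <- cohort_schema()
  tables <- list(sessions = sessions, trials = trials, motion = motion,
                 questionnaires = questionnaires)
  out <- purrr::imap(tables, function(tab, name) {
    if (is.null(tab)) return(empty_cohort_table(name))
    assert_cols(tab, schema[[name]], name)
    as_tibble(tab)[schema[[name]]]
  })
  structure(out, class = "nav_cohort")
}

#' @export
print.nav_cohort <- function(x, ...) {
  n_part <- length(unique(x$sessions$participant_id))
  cat(sprintf("<nav_cohort> %d session(s) from %d participant(s)\n",
              nrow(x$sessions), n_part))
  cat(sprintf("  trials: %d   motion samples: %d   questionnaire items: %d\n",
              nrow(x$trials), nrow(x$motion), nrow(x$questionnaires)))
  invisible(x)
}

#' Read a cohort from a directory of session logs
#'
#' Reads the delimited session-log format (see [cohort_schema()]). An
#' existing directory with none of the expected files yields an empty
#' cohort, not an error. Malformed rows raise a parse error naming file,
#' line and column; structural violations (duplicate trial keys,
#' non-monotone timestamps, non-finite coordinates) raise a validation
#' error when `validate = TRUE`.
#'
#' @param path directory containing `trials.csv`, `motion.csv`,
#'   `sessions.csv`, `questionnaires.csv` (any subset).
#' @param validate abort on structural invariant violations (default TRUE).
#' @return a [nav_cohort()].
#' @export
read_cohort <- function(path, validate = TRUE) {
  if (!dir.exists(path)) {
    input_error(sprintf("Directory not found: '%s'.", path))
  }
  types <- cohort_col_types()
  tables <- purrr::imap(cohort_schema(), function(cols, name) {
    file <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(file)) return(empty_cohort_table(name))
    tab <- suppressWarnings(
      readr::read_csv(file, comment = "#", col_types = types[[name]],
                      progress = FALSE)
    )
    probs <- readr::problems(tab)
    if (nrow(probs) > 0) {
      p <- probs[1, ]
      abort(sprintf(
        "Parse error in '%s' at line %d, column %d: expected %s, got '%s'.",
        file, p$row, p$col, p$expected, p$actual),
        class = "navassess_parse_error")
    }
    tab
  })
  cohort <- nav_cohort(tables$sessions, tables$trials, tables$motion,
                       tables$questionnaires)
  if (validate) {
    bad <- dplyr::filter(validate_sessions(cohort), .data$severity == "error")
    if (nrow(bad) > 0) {
      abort(paste0("Session logs violate structural invariants:\n",
                   paste0("  - ", bad$detail, collapse = "\n")),
            class = "navassess_validation_error")
    }
  }
  cohort
}

#' Write a cohort to a directory
#'
#' Serializes the four tables as comma-separated text with a versioned
#' comment header, numeric fields at full (round-trip) precision. The
#' output is readable by [read_cohort()]; partial (aborted) sessions are
#' preserved verbatim.
#'
#' @param cohort a [nav_cohort()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "nav_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) {
    abort(sprintf("Cannot create output directory '%s'.", path),
          class = "navassess_io_error")
  }
  for (name in names(cohort_schema())) {
    file <- file.path(path, paste0(name, ".csv"))
    readr::write_lines(LOG_FORMAT_HEADER, file)
    readr::write_csv(cohort[[name]], file, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  }
  invisible(path)
}

#' Validate session-log invariants
#'
#' Checks every structural invariant of the session-log model and returns
#' violations as data (one row each), never as conditions. Severity
#' `"error"` marks violations that make downstream analysis unsound
#' (non-finite coordinates, duplicate trial keys, non-monotone
#' timestamps); `"warning"` marks quality findings (sampling gaps,
#' unexpected trial counts, duration/trace mismatches, inconsistent
#' landmark labels, out-of-range Likert responses).
#'
#' @param cohort a [nav_cohort()].
#' @param max_gap maximum tolerated timestamp gap, in multiples of the
#'   nominal 10 ms interval (default 2: gaps above 20 ms are flagged).
#' @param duration_tolerance tolerated absolute difference, in minutes,
#'   between a stored phase duration and the extent of its motion trace
#'   (default 0.02 min, i.e. two 10 ms samples plus slack).
#' @return a tibble with columns `participant_id`, `condition`, `table`,
#'   `check`, `severity`, `detail`; zero rows iff all invariants hold.
#' @export
validate_sessions <- function(cohort, max_gap = 2, duration_tolerance = 0.02) {
  stopifnot(inherits(cohort, "nav_cohort"))
  v <- list()
  add <- function(pid, cond, table, check, severity, detail) {
    tibble(participant_id = pid, condition = cond, table = table,
           check = check, severity = severity, detail = detail)
  }

  tr <- cohort$trials
  if (nrow(tr) > 0) {
    num <- c("enc_x", "enc_z", "rec_x", "rec_z", "recall_latency")
    bad <- !apply(is.finite(as.matrix(tr[num])), 1, all)
    if (any(bad)) {
      rows <- which(bad)
      v[[length(v) + 1]] <- add(
        tr$participant_id[rows], tr$condition[rows], "trials",
        "finite_coordinates", "error",
        sprintf("trials row %d: non-finite coordinate or latency", rows))
    }
    dup <- tr |>
      count(.data$participant_id, .data$condition, .data$item_id,
            .data$repetition, name = "n_rows") |>
      filter(.data$n_rows > 1)
    if (nrow(dup) > 0) {
      v[[length(v) + 1]] <- add(
        dup$participant_id, dup$condition, "trials", "unique_trial_key",
        "error",
        sprintf("participant %s, %s: duplicated (item_id=%d, repetition=%d)",
                dup$participant_id, dup$condition, dup$item_id,
                dup$repetition))
    }
    lm_bad <- tr |>
      group_by(.data$participant_id, .data$condition, .data$repetition) |>
      summarise(n_landmarks = dplyr::n_distinct(.data$landmark),
                .groups = "drop") |>
      filter(.data$n_landmarks > 1)
    if (nrow(lm_bad) > 0) {
      v[[length(v) + 1]] <- add(
        lm_bad$participant_id, lm_bad$condition, "trials",
        "landmark_constant_in_block", "warning",
        sprintf("participant %s, %s: repetition block %d mixes landmark labels",
                lm_bad$participant_id, lm_bad$condition, lm_bad$repetition))
    }
  }

  se <- cohort$sessions
  if (nrow(se) > 0) {
    counts <- tr |>
      count(.data$participant_id, .data$condition, name = "n_trials")
    chk <- se |>
      left_join(counts, by = c("participant_id", "condition")) |>
      mutate(n_trials = dplyr::coalesce(.data$n_trials, 0L)) |>
      filter(.data$completed, .data$n_trials != 16L)
    if (nrow(chk) > 0) {
      v[[length(v) + 1]] <- add(
        chk$participant_id, chk$condition, "sessions", "trial_count",
        "warning",
        sprintf("participant %s, %s: completed session has %d trials (expected 16)",
                chk$participant_id, chk$condition, chk$n_trials))
    }
  }

  mo <- cohort$motion
  if (nrow(mo) > 0) {
    by_trace <- mo |>
      group_by(.data$participant_id, .data$condition, .data$phase)
    mono <- by_trace |>
      summarise(ok = all(diff(.data$t_ms) > 0), .groups = "drop") |>
      filter(!.data$ok)
    if (nrow(mono) > 0) {
      v[[length(v) + 1]] <- add(
        mono$participant_id, mono$condition, "motion",
        "monotone_timestamps", "error",
        sprintf("participant %s, %s %s trace: timestamps not strictly increasing",
                mono$participant_id, mono$condition, mono$phase))
    }
    gaps <- by_trace |>
      summarise(n_gaps = sum(diff(.data$t_ms) > max_gap * SAMPLE_MS),
                .groups = "drop") |>
      filter(.data$n_gaps > 0)
    if (nrow(gaps) > 0) {
      v[[length(v) + 1]] <- add(
        gaps$participant_id, gaps$condition, "motion", "sampling_gap",
        "warning",
        sprintf("participant %s, %s %s trace: %d gap(s) exceeding %d ms",
                gaps$participant_id, gaps$condition, gaps$phase, gaps$n_gaps,
                as.integer(max_gap * SAMPLE_MS)))
    }
    if (nrow(se) > 0) {
      extents <- by_trace |>
        summarise(extent_min = (max(.data$t_ms) - min(.data$t_ms)) / 60000 +
                    SAMPLE_MS / 60000,
                  .groups = "drop") |>
        tidyr::pivot_wider(names_from = "phase", values_from = "extent_min")
      chk <- se |> inner_join(extents, by = c("participant_id", "condition"))
      if ("encoding" %in% names(chk)) {
        bad <- filter(chk, abs(.data$encoding - .data$encoding_duration) >
                        duration_tolerance)
        if (nrow(bad) > 0) {
          v[[length(v) + 1]] <- add(
            bad$participant_id, bad$condition, "sessions",
            "duration_trace_consistency", "warning",
            sprintf("participant %s, %s: encoding_duration %.4f min vs trace extent %.4f min",
                    bad$participant_id, bad$condition, bad$encoding_duration,
                    bad$encoding))
        }
      }
      if ("recall" %in% names(chk)) {
        bad <- filter(chk, abs(.data$recall - .data$recall_duration) >
                        duration_tolerance)
        if (nrow(bad) > 0) {
          v[[length(v) + 1]] <- add(
            bad$participant_id, bad$condition, "sessions",
            "duration_trace_consistency", "warning",
            sprintf("participant %s, %s: recall_duration %.4f min vs trace extent %.4f min",
                    bad$participant_id, bad$condition, bad$recall_duration,
                    bad$recall))
        }
      }
    }
  }

  qu <- cohort$questionnaires
  if (nrow(qu) > 0) {
    bad <- filter(qu, !.data$response %in% 1:5)
    if (nrow(bad) > 0) {
      v[[length(v) + 1]] <- add(
        bad$participant_id, bad$condition, "questionnaires", "likert_range",
        "warning",
        sprintf("participant %s, %s: %s item %d response %s outside 1-5",
                bad$participant_id, bad$condition, bad$instrument, bad$item,
                as.character(bad$response)))
    }
    sus_n <- qu |>
      filter(.data$instrument == "SUS") |>
      count(.data$participant_id, .data$condition, name = "n_items") |>
      filter(.data$n_items != 10L)
    if (nrow(sus_n) > 0) {
      v[[length(v) + 1]] <- add(
        sus_n$participant_id, sus_n$condition, "questionnaires",
        "sus_item_count", "warning",
        sprintf("participant %s, %s: SUS has %d items (expected 10)",
                sus_n$participant_id, sus_n$condition, sus_n$n_items))
    }
  }

  if (length(v) == 0) {
    return(tibble(participant_id = character(0), condition = character(0),
                  table = character(0), check = character(0),
                  severity = character(0), detail = character(0)))
  }
  bind_rows(v)
}
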