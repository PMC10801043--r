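# End-to-end pipeline: ingest -> score -> metrics -> statistics -> report.

#' Run the full analysis pipeline
#'
#' Takes a cohort (a [nav_cohort()], a directory of session logs, or
#' nothing — in which case a synthetic cohort is generated from
#' `config`), and produces every report table of the analysis:
#' questionnaire summaries with paired tests, the landmark x condition
#' recall-error table with its mixed-effects ANOVAs, the phase x
#' condition movement-magnitude table with its ANOVA, encoding/recall
#' Jaccard similarity, phase durations, and the cross-solution
#' usability comparison.
#'
#' @param input a [nav_cohort()], a path to a session-log directory, or
#'   NULL to simulate from `config`.
#' @param config a [cohort_config()] (used when `input` is NULL; its
#'   `correct_radius` also sets the correctness radius everywhere).
#' @param seed optional integer overriding `config$seed`.
#' @param jaccard_bin_width histogram bin width for the Jaccard index
#'   (default 0.05 magnitude units).
#' @param jaccard_method variant passed to [jaccard_similarity()].
#' @param angle_direction passed to [polar_error()].
#' @param reference_solutions optional tibble of previously published
#'   solutions to place alongside the two conditions in the comparison
#'   table (columns `solution`, `sus_mean`, `sus_sd`, `itc_ne_mean`,
#'   `itc_ne_sd`); NULL for none.
#' @return an object of class `study_report`: a named list of tibbles
#'   (`sus_table`, `itc_ne_table`, `error_table`, `error_anova`,
#'   `vt_table`, `vt_anova`, `jaccard_table`, `jaccard_summary`,
#'   `duration_summary`, `comparison_table`, `log`).
#' @export
run_pipeline <- function(input = NULL, config = cohort_config(),
                         seed = NULL, jaccard_bin_width = 0.05,
                         jaccard_method = "weighted",
                         angle_direction = "encoding_to_recall",
                         reference_solutions = NULL) {
  log <- list()
  note <- function(stage, detail) {
    log[[length(log) + 1]] <<- tibble(stage = stage, detail = detail)
  }

  if (is.null(input)) {
    if (!is.null(seed)) {
      config$seed <- as.integer(seed)
    }
    cohort <- simulate_cohort(config)
    note("ingest", sprintf("simulated cohort (seed %d): %d sessions",
                           config$seed, nrow(cohort$sessions)))
  } else if (inherits(input, "nav_cohort")) {
    cohort <- input
    note("ingest", sprintf("in-memory cohort: %d sessions",
                           nrow(cohort$sessions)))
  } else if (is.character(input)) {
    cohort <- read_cohort(input)
    note("ingest", sprintf("read '%s': %d sessions", input,
                           nrow(cohort$sessions)))
  } else {
    input_error("`input` must be a nav_cohort, a directory path, or NULL.")
  }
  radius <- config$correct_radius %||% 6

  all_pids <- unique(c(cohort$sessions$participant_id,
                       cohort$questionnaires$participant_id))
  per_part <- cohort$sessions |> count(.data$participant_id)
  note("ingest", sprintf(
    "%d participant(s); %d with both conditions, %d with one, %d with none",
    length(all_pids), sum(per_part$n == 2), sum(per_part$n == 1),
    length(all_pids) - nrow(per_part)))

  # --- questionnaires -------------------------------------------------
  scores <- score_questionnaires(cohort$questionnaires)
  note("score", sprintf("%d questionnaire scores from %d item responses",
                        nrow(scores), nrow(cohort$questionnaires)))
  inst_table <- function(inst) {
    sc <- filter(scores, .data$instrument == inst)
    summ <- sc |>
      group_by(.data$condition) |>
      summarise(n = dplyr::n(), mean = mean(.data$score),
                sd = sd(.data$score), .groups = "drop")
    if (inst == "SUS") summ <- mutate(summ, band = sus_band(.data$mean))
    tests <- if (length(unique(sc$condition)) == 2) {
      compare_conditions(sc, "score")
    } else NULL
    list(summary = summ, tests = tests)
  }
  sus <- inst_table("SUS")
  itc <- inst_table("ITC_SOPI_NE")

  # --- spatial memory -------------------------------------------------
  trials <- cohort$trials |>
    polar_error(angle_direction = angle_direction) |>
    classify_recall(radius = radius)
  error_table <- summarize_errors(trials) |>
    left_join(trials |>
                group_by(.data$landmark, .data$condition) |>
                summarise(prop_correct = mean(.data$correct),
                          .groups = "drop"),
              by = c("landmark", "condition"))
  error_anova <- list(
    r = lmm_anova(trials, "r", c("landmark", "condition")),
    theta = lmm_anova(filter(trials, !is.na(.data$theta_deg)),
                      "theta_deg", c("landmark", "condition"))
  )
  note("metrics", sprintf(
    "%d trials; %d correct within radius %g; %d excluded from angle stats (r = 0)",
    nrow(trials), sum(trials$correct), radius,
    sum(is.na(trials$theta_deg))))

  # --- motion ---------------------------------------------------------
  vt_session <- magnitude_series(cohort$motion) |>
    group_by(.data$participant_id, .data$condition, .data$phase) |>
    summarise(v_mean = mean(.data$v), .groups = "drop")
  vt_table <- vt_session |>
    group_by(.data$phase, .data$condition) |>
    summarise(n = dplyr::n(), mean_vt = mean(.data$v_mean),
              sd_vt = sd(.data$v_mean), .groups = "drop")
  vt_anova <- lmm_anova(vt_session, "v_mean", c("phase", "condition"))

  jaccard_table <- summarize_jaccard(cohort$motion,
                                     bin_width = jaccard_bin_width,
                                     method = jaccard_method)
  jaccard_summary <- jaccard_table |>
    group_by(.data$condition) |>
    summarise(n = dplyr::n(), mean = mean(.data$jaccard),
              sd = sd(.data$jaccard), .groups = "drop")
  jaccard_tests <- if (length(unique(jaccard_table$condition)) == 2 &&
                       nrow(tidyr::drop_na(tidyr::pivot_wider(
                         jaccard_table, names_from = "condition",
                         values_from = "jaccard"))) >= 2) {
    compare_conditions(jaccard_table, "jaccard")
  } else NULL

  durations <- summarize_durations(cohort$motion)
  duration_summary <- durations |>
    group_by(.data$phase, .data$condition) |>
    summarise(n = dplyr::n(), mean_min = mean(.data$duration_min),
              sd_min = sd(.data$duration_min), .groups = "drop")
  enc_dur <- filter(durations, .data$phase == "encoding")
  duration_tests <- if (length(unique(enc_dur$condition)) == 2 &&
                        nrow(tidyr::drop_na(tidyr::pivot_wider(
                          select(enc_dur, -"phase", -"n_samples"),
                          names_from = "condition",
                          values_from = "duration_min"))) >= 2) {
    compare_conditions(enc_dur, "duration_min")
  } else NULL
  note("motion", sprintf("%d motion samples in %d traces",
                         nrow(cohort$motion), nrow(durations)))

  # --- cross-solution comparison --------------------------------------
  computed <- sus$summary |>
    select("condition", sus_mean = "mean", sus_sd = "sd") |>
    left_join(itc$summary |>
                select("condition", itc_ne_mean = "mean",
                       itc_ne_sd = "sd"),
              by = "condition") |>
    rename(solution = "condition")
  comparison_table <- bind_rows(
    if (!is.null(reference_solutions)) as_tibble(reference_solutions),
    computed
  )

  note("report", "all tables assembled")
  structure(list(
    sus_table = sus$summary, sus_tests = sus$tests,
    itc_ne_table = itc$summary, itc_ne_tests = itc$tests,
    error_table = error_table,
    error_anova_r = tidy(error_anova$r),
    error_anova_theta = tidy(error_anova$theta),
    error_anova_fits = error_anova,
    vt_table = vt_table, vt_anova = tidy(vt_anova), vt_anova_fit = vt_anova,
    jaccard_table = jaccard_table, jaccard_summary = jaccard_summary,
    jaccard_tests = jaccard_tests,
    duration_summary = duration_summary, duration_tests = duration_tests,
    comparison_table = comparison_table,
    trials = trials,
    log = bind_rows(log)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("-- SUS by condition --\n")
  print(as.data.frame(x$sus_table), row.names = FALSE, digits = 4)
  cat("-- ITC-SOPI negative effects by condition --\n")
  print(as.data.frame(x$itc_ne_table), row.names = FALSE, digits = 4)
  cat("-- recall error by landmark x condition --\n")
  print(as.data.frame(x$error_table), row.names = FALSE, digits = 4)
  cat("-- movement magnitude by phase x condition --\n")
  print(as.data.frame(x$vt_table), row.names = FALSE, digits = 4)
  cat("-- encoding/recall Jaccard similarity --\n")
  print(as.data.frame(x$jaccard_summary), row.names = FALSE, digits = 4)
  invisible(x)
}

report_table_names <- function() {
  c("sus_table", "sus_tests", "itc_ne_table", "itc_ne_tests",
    "error_table", "error_anova_r", "error_anova_theta", "vt_table",
    "vt_anova", "jaccard_table", "jaccard_summary", "jaccard_tests",
    "duration_summary", "comparison_table", "log")
}

#' Write a study report to a directory
#'
#' Serializes every report table as a comma-separated file plus a
#' human-readable `summary.txt`. Writing is all-or-nothing: on any
#' failure, partially written files are removed.
#'
#' @param report a `study_report` from [run_pipeline()].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  tryCatch({
    for (name in report_table_names()) {
      tab <- report[[name]]
      if (is.null(tab)) next
      file <- file.path(path, paste0(name, ".csv"))
      readr::write_csv(as_tibble(tab), file, progress = FALSE)
      written <- c(written, file)
    }
    sfile <- file.path(path, "summary.txt")
    written <- c(written, sfile)
    con <- file(sfile, open = "wt")
    on.exit(close(con), add = TRUE)
    sink(con)
    print(report)
    sink()
  }, error = function(e) {
    try(sink(), silent = TRUE)
    unlink(written)
    abort(sprintf("Failed writing report to '%s': %s", path,
                  conditionMessage(e)),
          class = "navassess_io_error")
  })
  invisible(path)
}

#' Import a deposited study archive
#'
#' Best-effort adapter from an unpacked external data deposit into the
#' package's cohort model. Directories already laid out in the package's
#' own session-log format are read directly; any other layout raises an
#' adapter error listing the files found, so the mapping can be extended
#' once the archive structure is known.
#'
#' @param path directory containing the unpacked archive.
#' @return a [nav_cohort()].
#' @export
import_deposited <- function(path) {
  if (!dir.exists(path)) {
    input_error(sprintf("Directory not found: '%s'.", path))
  }
  files <- list.files(path, recursive = TRUE)
  own <- paste0(names(cohort_schema()), ".csv")
  if (any(own %in% files)) {
    return(read_cohort(path))
  }
  abort(paste0(
    "Unrecognized archive layout; no adapter matches. Files found: ",
    if (length(files) == 0) "(none)" else
      paste(utils::head(files, 20), collapse = ", ")),
    class = "navassess_adapter_error")
}
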