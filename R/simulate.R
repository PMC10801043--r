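# Synthetic cohort generator.
#
# Emulates the study design: a within-subject usability protocol in which
# each participant attempts an immersive and a semi-immersive VR session,
# relocating 4 objects x 4 repetitions per session, with a landmark
# manipulation (allocentric vs egocentric recall blocks), 100 Hz foot-pad
# telemetry, and SUS / ITC-SOPI negative-effects questionnaires.
#
# Ground truth is known by construction: recall displacement is isotropic
# bivariate Gaussian per (landmark x condition) cell, so recall error r is
# Rayleigh(sigma) with mean sigma * sqrt(pi/2), the correct-recall fraction
# is 1 - exp(-radius^2 / (2 sigma^2)), and the angular deviation is uniform
# on [0, 360). These closed forms drive the parameter-recovery tests.

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions: 7 participants of whom 5
#' complete both conditions, 1 completes only the semi-immersive session
#' and 1 completes neither (cybersickness dropouts); 4 items x 4
#' repetitions per session; per-cell recall-displacement scale derived
#' from the reported cell mean errors via the Rayleigh relation
#' `sigma = mean_r / sqrt(pi/2)`; encoding durations 10.3 (SD 3.21) min
#' immersive and 8.51 (SD 2.29) min semi-immersive; questionnaire targets
#' SUS 65 (22.97) / 69.17 (25.52) and ITC-SOPI-NE 2.03 (0.91) /
#' 1.53 (0.56) for immersive / semi-immersive.
#'
#' @param n_participants number of participants (>= 1).
#' @param dropout_pattern character vector of length `n_participants` with
#'   values `"both"`, `"semi_only"` or `"none"`: which sessions each
#'   participant completes.
#' @param displacement_sigma tibble with columns `landmark`, `condition`,
#'   `sigma` (virtual units): scale of the isotropic Gaussian recall
#'   displacement per cell.
#' @param item_layout_radius radius (virtual units) of the circle on which
#'   the four items sit.
#' @param motion_model list with `mean_reversion_rate` (1/s), `volatility`
#'   (1/sqrt(s)) and `clip` (saturation limit) for the pad-tilt process.
#' @param encoding_duration,recall_duration tibbles with columns
#'   `condition`, `mean`, `sd` (minutes).
#' @param questionnaire_targets tibble with columns `instrument`
#'   (`"SUS"` or `"ITC_SOPI_NE"`), `condition`, `mean`, `sd`.
#' @param n_itc_items number of negative-effects items administered.
#' @param correct_radius correctness radius in virtual units (default 6:
#'   a recall within 6 or fewer units of the item counts as correct).
#' @param seed integer root seed; per-participant/per-stream substreams
#'   are derived with [substream_seed()] so regenerating one participant
#'   never perturbs the others.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 7,
                          dropout_pattern = c(rep("both", 5), "semi_only",
                                              "none"),
                          displacement_sigma = default_displacement_sigma(),
                          item_layout_radius = 20,
                          motion_model = list(mean_reversion_rate = 2,
                                              volatility = 0.53,
                                              clip = 1),
                          encoding_duration = tibble(
                            condition = condition_levels(),
                            mean = c(10.3, 8.51),
                            sd = c(3.21, 2.29)),
                          recall_duration = tibble(
                            condition = condition_levels(),
                            mean = c(6, 6),
                            sd = c(2, 2)),
                          questionnaire_targets = default_questionnaire_targets(),
                          n_itc_items = 6,
                          correct_radius = 6,
                          seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              dropout_pattern = dropout_pattern,
              displacement_sigma = as_tibble(displacement_sigma),
              item_layout_radius = item_layout_radius,
              motion_model = motion_model,
              encoding_duration = as_tibble(encoding_duration),
              recall_duration = as_tibble(recall_duration),
              questionnaire_targets = as_tibble(questionnaire_targets),
              n_itc_items = as.integer(n_itc_items),
              correct_radius = correct_radius,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Default per-cell recall-displacement scales
#'
#' Rayleigh scales recovered from the study's reported cell mean errors
#' (mean_r / sqrt(pi/2)).
#' @return tibble with columns `landmark`, `condition`, `sigma`.
#' @export
default_displacement_sigma <- function() {
  tibble(
    landmark = rep(landmark_levels(), each = 2),
    condition = rep(condition_levels(), times = 2),
    # cell mean errors: allo/imm 21.19, allo/semi 20.70,
    #                   ego/imm  20.55, ego/semi  26.47
    sigma = c(21.19, 20.70, 20.55, 26.47) / sqrt(pi / 2)
  )
}

#' Default questionnaire generation targets
#' @return tibble with columns `instrument`, `condition`, `mean`, `sd`.
#' @export
default_questionnaire_targets <- function() {
  tibble(
    instrument = rep(c("SUS", "ITC_SOPI_NE"), each = 2),
    condition = rep(condition_levels(), times = 2),
    mean = c(65, 69.17, 2.03, 1.53),
    sd = c(22.97, 25.52, 0.91, 0.56)
  )
}

validate_cohort_config <- function(cfg) {
  bad <- function(msg) abort(paste0("Invalid cohort config: ", msg),
                             class = "navassess_config_error")
  if (cfg$n_participants < 1) bad("n_participants must be >= 1.")
  if (length(cfg$dropout_pattern) != cfg$n_participants)
    bad("dropout_pattern length must equal n_participants.")
  if (!all(cfg$dropout_pattern %in% c("both", "semi_only", "none")))
    bad("dropout_pattern values must be 'both', 'semi_only' or 'none'.")
  assert_cols(cfg$displacement_sigma, c("landmark", "condition", "sigma"),
              "displacement_sigma")
  if (any(cfg$displacement_sigma$sigma < 0)) bad("sigma values must be >= 0.")
  cells <- with(cfg$displacement_sigma, paste(landmark, condition))
  need <- as.vector(outer(landmark_levels(), condition_levels(), paste))
  if (!all(need %in% cells)) bad("displacement_sigma must cover all 4 cells.")
  mm <- cfg$motion_model
  if (!all(c("mean_reversion_rate", "volatility", "clip") %in% names(mm)))
    bad("motion_model needs mean_reversion_rate, volatility, clip.")
  if (mm$clip <= 0) bad("motion clip must be > 0.")
  if (mm$volatility < 0 || mm$mean_reversion_rate < 0)
    bad("motion volatility and mean_reversion_rate must be >= 0.")
  for (tab in list(cfg$encoding_duration, cfg$recall_duration)) {
    assert_cols(tab, c("condition", "mean", "sd"), "duration table")
    if (any(tab$mean <= 0)) bad("durations must be > 0.")
    if (any(tab$sd < 0)) bad("duration SDs must be >= 0.")
  }
  assert_cols(cfg$questionnaire_targets,
              c("instrument", "condition", "mean", "sd"),
              "questionnaire_targets")
  if (any(cfg$questionnaire_targets$sd < 0)) bad("target SDs must be >= 0.")
  if (cfg$correct_radius <= 0) bad("correct_radius must be > 0.")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d participants (%s), seed %d\n",
              x$n_participants,
              paste(table(factor(x$dropout_pattern,
                                 c("both", "semi_only", "none"))),
                    c("both", "semi-only", "none"), collapse = " / "),
              x$seed))
  invisible(x)
}

# stream codes for substream_seed()
STREAM_TRIALS   <- 1L
STREAM_MOTION_E <- 2L
STREAM_MOTION_R <- 3L
STREAM_QUEST    <- 4L
STREAM_DURATION <- 5L

#' Generate a synthetic cohort
#'
#' Deterministic given `cfg$seed`. Completed sessions carry 16 trials
#' (4 items seen in each of 4 recall blocks); each recall block is tagged
#' with one landmark label (two allocentric and two egocentric blocks per
#' session, in random order, mirroring the random landmark presentation).
#' Recall coordinates are the encoding coordinates plus an isotropic
#' bivariate Gaussian displacement with the cell's sigma. Motion traces
#' are clipped mean-reverting (discrete Ornstein-Uhlenbeck) tilt processes
#' sampled at 100 Hz spanning the drawn phase durations. Questionnaire
#' items are drawn from a participant-level latent Gaussian aimed at the
#' configured instrument targets, then rounded and clamped into 1-5.
#' Questionnaires are produced for every participant in both conditions
#' (participants rate sessions they attempted even when aborting them).
#'
#' @param cfg a [cohort_config()].
#' @return a [nav_cohort()].
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  if (!inherits(cfg, "cohort_config")) {
    cfg <- do.call(cohort_config, cfg)
  }
  validate_cohort_config(cfg)
  pids <- sprintf("P%02d", seq_len(cfg$n_participants))

  sessions <- list(); trials <- list(); motion <- list(); quest <- list()
  for (i in seq_len(cfg$n_participants)) {
    conds <- switch(cfg$dropout_pattern[i],
                    both = condition_levels(),
                    semi_only = "semi_immersive",
                    none = character(0))
    for (cond in conds) {
      ci <- match(cond, condition_levels())
      tr <- simulate_session_trials(cfg, pids[i], cond,
                                    substream_seed(cfg$seed, i,
                                                   10L * ci + STREAM_TRIALS))
      durs <- simulate_durations(cfg, cond,
                                 substream_seed(cfg$seed, i,
                                                10L * ci + STREAM_DURATION))
      enc <- simulate_motion_trace(cfg$motion_model, durs["encoding"],
                                   substream_seed(cfg$seed, i,
                                                  10L * ci + STREAM_MOTION_E))
      rec <- simulate_motion_trace(cfg$motion_model, durs["recall"],
                                   substream_seed(cfg$seed, i,
                                                  10L * ci + STREAM_MOTION_R))
      mo <- bind_rows(mutate(enc, phase = "encoding"),
                      mutate(rec, phase = "recall")) |>
        mutate(participant_id = pids[i], condition = cond) |>
        select("participant_id", "condition", "phase", "t_ms",
               "pitch_y", "yaw_z")
      sessions[[length(sessions) + 1]] <- tibble(
        participant_id = pids[i], condition = cond, completed = TRUE,
        encoding_duration = nrow(enc) / SAMPLES_PER_MINUTE,
        recall_duration = nrow(rec) / SAMPLES_PER_MINUTE)
      trials[[length(trials) + 1]] <- tr
      motion[[length(motion) + 1]] <- mo
    }
    for (cond in condition_levels()) {
      ci <- match(cond, condition_levels())
      quest[[length(quest) + 1]] <- simulate_questionnaires(
        cfg, pids[i], cond,
        substream_seed(cfg$seed, i, 10L * ci + STREAM_QUEST))
    }
  }
  nav_cohort(sessions = bind_rows(sessions), trials = bind_rows(trials),
             motion = bind_rows(motion), questionnaires = bind_rows(quest))
}

# Fixed item layout: 4 items evenly spaced on a circle of the configured
# radius, shared by all sessions (the environment does not move).
item_positions <- function(radius) {
  ang <- 2 * pi * (0:3) / 4
  tibble(item_id = 1:4, enc_x = radius * cos(ang), enc_z = radius * sin(ang))
}

simulate_session_trials <- function(cfg, pid, cond, seed) {
  items <- item_positions(cfg$item_layout_radius)
  sig <- cfg$displacement_sigma |> filter(.data$condition == cond)
  sigma_of <- setNames(sig$sigma, sig$landmark)
  withr::with_seed(seed, {
    blocks <- sample(rep(landmark_levels(), each = 2))
    purrr::map_dfr(1:4, function(rep_i) {
      lm <- blocks[rep_i]
      s <- sigma_of[[lm]]
      order_i <- sample(4L)
      tibble(
        participant_id = pid, condition = cond, landmark = lm,
        item_id = items$item_id[order_i], repetition = rep_i,
        enc_x = items$enc_x[order_i], enc_z = items$enc_z[order_i],
        recall_latency = pmax(1, rnorm(4, mean = 20, sd = 8))
      ) |>
        mutate(rec_x = .data$enc_x + rnorm(4, 0, s),
               rec_z = .data$enc_z + rnorm(4, 0, s)) |>
        select("participant_id", "condition", "landmark", "item_id",
               "repetition", "enc_x", "enc_z", "rec_x", "rec_z",
               "recall_latency")
    })
  })
}

simulate_durations <- function(cfg, cond, seed) {
  e <- filter(cfg$encoding_duration, .data$condition == cond)
  r <- filter(cfg$recall_duration, .data$condition == cond)
  withr::with_seed(seed, {
    c(encoding = max(rnorm(1, e$mean, e$sd), 0.05, e$mean / 4),
      recall = max(rnorm(1, r$mean, r$sd), 0.05, r$mean / 4))
  })
}

#' Simulate one foot-motion-pad trace
#'
#' Discrete mean-reverting (AR(1)/Ornstein-Uhlenbeck) process per tilt
#' axis at 100 Hz, saturated at +/- `clip`: the pad tilt wanders around
#' neutral and cannot exceed its mechanical range. The trace has exactly
#' `round(duration_min * 6000)` samples.
#'
#' @param model list with `mean_reversion_rate` (1/s), `volatility`
#'   (1/sqrt(s)), `clip`.
#' @param duration_min trace duration in minutes.
#' @param seed integer seed.
#' @return tibble with columns `t_ms`, `pitch_y`, `yaw_z`.
#' @export
simulate_motion_trace <- function(model, duration_min, seed) {
  n <- max(2L, as.integer(round(duration_min * SAMPLES_PER_MINUTE)))
  dt <- SAMPLE_MS / 1000
  a <- max(0, 1 - model$mean_reversion_rate * dt)
  s <- model$volatility * sqrt(dt)
  withr::with_seed(seed, {
    ou <- function() {
      x <- as.numeric(stats::filter(rnorm(n, 0, s), a, method = "recursive"))
      pmin(pmax(x, -model$clip), model$clip)
    }
    tibble(t_ms = (seq_len(n) - 1L) * SAMPLE_MS, pitch_y = ou(), yaw_z = ou())
  })
}

simulate_questionnaires <- function(cfg, pid, cond, seed) {
  targets <- filter(cfg$questionnaire_targets, .data$condition == cond)
  sus_t <- filter(targets, .data$instrument == "SUS")
  itc_t <- filter(targets, .data$instrument == "ITC_SOPI_NE")
  withr::with_seed(seed, {
    # SUS: participant-level latent usability u in [0, 100]; per-item scored
    # contribution c_i ~ round(u/25 + noise) in 0..4, mapped back to the
    # Likert response so that standard SUS scoring recovers ~u.
    u <- min(max(rnorm(1, sus_t$mean, sus_t$sd), 0), 100)
    contrib <- pmin(pmax(round(u / 25 + rnorm(10, 0, 0.6)), 0), 4)
    odd <- seq(1, 9, by = 2)
    sus_resp <- integer(10)
    sus_resp[odd] <- contrib[odd] + 1L
    sus_resp[-odd] <- 5L - contrib[-odd]
    # ITC-SOPI NE: latent mean severity, item-level jitter, 1-5 Likert.
    m <- min(max(rnorm(1, itc_t$mean, itc_t$sd), 1), 5)
    itc_resp <- pmin(pmax(round(m + rnorm(cfg$n_itc_items, 0, 0.5)), 1), 5)
    bind_rows(
      tibble(participant_id = pid, condition = cond, instrument = "SUS",
             item = 1:10, response = as.integer(sus_resp)),
      tibble(participant_id = pid, condition = cond,
             instrument = "ITC_SOPI_NE", item = seq_len(cfg$n_itc_items),
             response = as.integer(itc_resp))
    )
  })
}

#' Frozen reference cohort
#'
#' A small, seed-pinned synthetic cohort used by the example-based tests:
#' the study's dropout structure (5 both / 1 semi-only / 1 none -> 11
#' sessions) with short motion traces so the fixture stays light. Identical
#' across platforms and calls.
#'
#' @return a [nav_cohort()].
#' @export
reference_cohort <- function() {
  cfg <- cohort_config(
    encoding_duration = tibble(condition = condition_levels(),
                               mean = c(0.20, 0.17), sd = c(0.04, 0.03)),
    recall_duration = tibble(condition = condition_levels(),
                             mean = c(0.12, 0.12), sd = c(0.02, 0.02)),
    seed = 104729L
  )
  simulate_cohort(cfg)
}
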