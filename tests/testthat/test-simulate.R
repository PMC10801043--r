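# Synthetic cohort generator: structure, determinism, and the closed-form
# ground truth of its displacement model.

test_that("the study dropout pattern yields 11 sessions from 7 participants", {
  co <- fixture_cohort()
  expect_identical(nrow(co$sessions), 11L)
  expect_identical(nrow(co$trials), 176L) # 11 completed sessions x 16 trials
  counts <- dplyr::count(co$sessions, participant_id)
  expect_identical(sum(counts$n == 2), 5L)
  expect_identical(sum(counts$n == 1), 1L)
  # questionnaires exist for all 7 participants in both conditions
  qn <- dplyr::distinct(co$questionnaires, participant_id, condition)
  expect_identical(nrow(qn), 14L)
})

test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(seed = 42L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  for (tab in names(cohort_schema())) {
    expect_identical(a[[tab]], b[[tab]], label = tab)
  }
  c2 <- simulate_cohort(cohort_config(seed = 43L))
  expect_false(identical(a$trials$rec_x, c2$trials$rec_x))
})

test_that("regenerating with more participants preserves earlier ones", {
  small <- simulate_cohort(cohort_config(
    n_participants = 3, dropout_pattern = rep("both", 3), seed = 7L))
  big <- simulate_cohort(cohort_config(
    n_participants = 5, dropout_pattern = rep("both", 5), seed = 7L))
  keep <- big$trials$participant_id %in% c("P01", "P02", "P03")
  expect_identical(big$trials[keep, ], small$trials)
})

test_that("zero displacement noise reproduces encoding locations exactly", {
  cfg <- cohort_config(
    displacement_sigma = dplyr::mutate(default_displacement_sigma(),
                                       sigma = 0),
    seed = 5L)
  co <- simulate_cohort(cfg)
  pe <- classify_recall(polar_error(co$trials))
  expect_true(all(pe$r == 0))
  expect_true(all(is.na(pe$theta_deg)))
  expect_true(all(pe$correct))
})

test_that("motion traces respect the clip bound and the 100 Hz contract", {
  co <- fixture_cohort()
  expect_true(all(abs(co$motion$pitch_y) <= 1))
  expect_true(all(abs(co$motion$yaw_z) <= 1))
  per_trace <- dplyr::summarise(
    dplyr::group_by(co$motion, participant_id, condition, phase),
    n = dplyr::n(), spacing_ok = all(diff(t_ms) == 10L), .groups = "drop")
  expect_true(all(per_trace$spacing_ok))
  # stored durations equal n_samples / 6000 minutes exactly
  joined <- dplyr::inner_join(
    tidyr::pivot_wider(per_trace, names_from = phase, values_from = n,
                       id_cols = c(participant_id, condition)),
    co$sessions, by = c("participant_id", "condition"))
  expect_equal(joined$encoding / 6000, joined$encoding_duration)
  expect_equal(joined$recall / 6000, joined$recall_duration)
})

test_that("recall error follows the configured Rayleigh law", {
  # many participants, one shared sigma -> tight closed-form checks
  sigma_true <- 10
  n_part <- 320L # 320 x 2 sessions x 16 trials = 10,240 trials
  cfg <- cohort_config(
    n_participants = n_part, dropout_pattern = rep("both", n_part),
    displacement_sigma = dplyr::mutate(default_displacement_sigma(),
                                       sigma = sigma_true),
    encoding_duration = tibble::tibble(condition = condition_levels(),
                                       mean = 0.02, sd = 0),
    recall_duration = tibble::tibble(condition = condition_levels(),
                                     mean = 0.02, sd = 0),
    seed = 11L)
  pe <- classify_recall(polar_error(simulate_cohort(cfg)$trials), radius = 6)
  n <- nrow(pe)
  expect_gte(n, 10000L)

  # mean r within 2% of the Rayleigh mean sigma * sqrt(pi/2)
  expect_lt(abs(mean(pe$r) / (sigma_true * sqrt(pi / 2)) - 1), 0.02)

  # correct fraction within binomial bounds of the Rayleigh CDF at radius 6
  p_true <- 1 - exp(-6^2 / (2 * sigma_true^2))
  expect_lt(abs(mean(pe$correct) - p_true),
            4 * sqrt(p_true * (1 - p_true) / n))

  # angles uniform on [0, 360): chi-square over 36 bins must not reject
  th <- pe$theta_deg[!is.na(pe$theta_deg)]
  chi <- suppressWarnings(
    chisq.test(tabulate(floor(th / 10) + 1, nbins = 36)))
  expect_gt(chi$p.value, 0.001)
})

test_that("theta uniformity holds across seeds (chi-square at alpha 0.001)", {
  seeds <- 101:120
  pass <- vapply(seeds, function(s) {
    withr::with_seed(s, {
      dx <- rnorm(10000, 0, 10)
      dz <- rnorm(10000, 0, 10)
    })
    trials <- tibble::tibble(enc_x = 0, enc_z = 0, rec_x = dx, rec_z = dz)
    th <- polar_error(trials)$theta_deg
    chi <- suppressWarnings(
      chisq.test(tabulate(floor(th / 10) + 1, nbins = 36)))
    chi$p.value > 0.001
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("questionnaire generation lands near its configured targets", {
  n <- 60L
  cfg <- cohort_config(
    n_participants = n, dropout_pattern = rep("both", n),
    encoding_duration = tibble::tibble(condition = condition_levels(),
                                       mean = 0.02, sd = 0),
    recall_duration = tibble::tibble(condition = condition_levels(),
                                     mean = 0.02, sd = 0),
    seed = 13L)
  co <- simulate_cohort(cfg)
  sc <- score_questionnaires(co$questionnaires)
  got <- dplyr::summarise(dplyr::group_by(sc, instrument, condition),
                          m = mean(score), s = sd(score), .groups = "drop")
  targets <- default_questionnaire_targets()
  joined <- dplyr::inner_join(got, targets,
                              by = c("instrument", "condition"))
  # means within ~2 SE of target (latent clamping biases slightly inward)
  expect_true(all(abs(joined$m - joined$mean) <
                    3 * joined$sd / sqrt(n) + 2))
  expect_true(all(sc$score[sc$instrument == "SUS"] %% 2.5 == 0))
  expect_true(all(dplyr::between(sc$score[sc$instrument == "ITC_SOPI_NE"],
                                 1, 5)))
})

test_that("invalid configurations are rejected before any generation", {
  expect_error(cohort_config(n_participants = 0),
               class = "navassess_config_error")
  expect_error(cohort_config(dropout_pattern = c("both", "maybe"),
                             n_participants = 2),
               class = "navassess_config_error")
  expect_error(
    cohort_config(displacement_sigma = dplyr::mutate(
      default_displacement_sigma(), sigma = -1)),
    class = "navassess_config_error")
  expect_error(
    cohort_config(motion_model = list(mean_reversion_rate = 2,
                                      volatility = 0.5, clip = 0)),
    class = "navassess_config_error")
})

test_that("the frozen reference cohort is valid and matches its Rayleigh means", {
  co <- fixture_cohort()
  expect_identical(nrow(validate_sessions(co)), 0L)
  cells <- summarize_errors(co$trials)
  truth <- dplyr::mutate(default_displacement_sigma(),
                         mean_true = sigma * sqrt(pi / 2),
                         se = sigma * sqrt((4 - pi) / 2))
  joined <- dplyr::inner_join(cells, truth, by = c("landmark", "condition"))
  expect_true(all(abs(joined$mean_r - joined$mean_true) <=
                    3 * joined$se / sqrt(joined$n_trials)))
})
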