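# Paired tests and the mixed-effects ANOVA.

test_that("paired t matches the textbook formula and its edge cases", {
  # zero mean difference -> t = 0, p = 1
  res <- paired_t(c(1, 2, 3, 5, 3), c(1, 2, 3, 4, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # constant nonzero difference -> degenerate variance error
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)),
               class = "navassess_degenerate_error")
  expect_error(paired_t(1, 2), class = "navassess_input_error")

  # 7-pair vectors vs independent textbook recomputation
  withr::with_seed(41, {
    for (i in 1:10) {
      x <- rnorm(7, 60, 20)
      y <- rnorm(7, 70, 20)
      got <- paired_t(x, y)
      want <- oracle_paired_t(x, y)
      expect_equal(got$statistic, want$t, tolerance = 1e-10)
      expect_equal(got$df, want$df)
      expect_equal(got$p, want$p, tolerance = 1e-10)
    }
  })
})

test_that("paired t is antisymmetric and drops incomplete pairs", {
  withr::with_seed(42, {
    x <- rnorm(9); y <- rnorm(9)
  })
  ab <- paired_t(x, y)
  ba <- paired_t(y, x)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p, ba$p)
  x[3] <- NA
  expect_identical(paired_t(x, y)$n_pairs, 8L)
})

test_that("Wilcoxon W follows the positive-rank-sum convention", {
  x <- 1:6
  all_neg <- wilcoxon_signed_rank(x, x + c(1, 2, 3, 1, 2, 3))
  expect_equal(all_neg$statistic, 0)
  all_pos <- wilcoxon_signed_rank(x + c(1, 2, 3, 1, 2, 3), x)
  expect_equal(all_pos$statistic, 21) # n(n+1)/2 for n = 6
  expect_error(wilcoxon_signed_rank(x, x), class = "navassess_input_error")
})

test_that("Wilcoxon exact p equals full sign enumeration for n <= 12", {
  withr::with_seed(43, {
    for (n in c(5, 8, 12)) {
      for (i in 1:5) {
        x <- round(rnorm(n, 0, 3), 2)
        y <- round(rnorm(n, 0.8, 3), 2)
        d <- x - y
        if (any(d == 0) || any(duplicated(rank(abs(d[d != 0]))))) next
        got <- wilcoxon_signed_rank(x, y)
        want <- oracle_wilcoxon_exact(x, y)
        expect_equal(got$statistic, want$w)
        expect_equal(got$p, want$p, tolerance = 1e-12)
      }
    }
  })
})

test_that("zero differences are dropped and surfaced as tied pairs", {
  x <- c(3, 4, 5, 6, 7, 8, 9)
  y <- c(3, 4, 6, 7, 8, 9, 10) # two tied pairs, rest negative
  res <- wilcoxon_signed_rank(x, y)
  expect_identical(res$tied_pairs, 2L)
  expect_identical(res$n_pairs, 7L)
  expect_equal(res$statistic, 0)
})

test_that("compare_conditions pairs by participant and reports both tests", {
  sc <- score_questionnaires(fixture_cohort()$questionnaires)
  sus <- dplyr::filter(sc, instrument == "SUS")
  out <- compare_conditions(sus, "score")
  expect_identical(out$method, c("paired_t", "wilcoxon_signed_rank"))
  expect_identical(out$n_pairs, c(7L, 7L))
  wide <- tidyr::pivot_wider(sus[c("participant_id", "condition", "score")],
                             names_from = condition, values_from = score)
  want <- oracle_paired_t(wide$immersive, wide$semi_immersive)
  expect_equal(out$statistic[1], want$t, tolerance = 1e-10)
})

test_that("lmm_anova reduces to the fixed-effects ANOVA without participant variance", {
  # every participant has identical balanced data -> the random-intercept
  # variance is estimated at the boundary (0) and the mixed F equals the
  # classic two-way fixed-effects F
  withr::with_seed(44, {
    cell <- expand.grid(landmark = c("allocentric", "egocentric"),
                        condition = c("immersive", "semi_immersive"),
                        rep = 1:4)
    cell$y <- rnorm(nrow(cell), 20, 5) +
      3 * (cell$landmark == "egocentric") +
      2 * (cell$condition == "immersive")
  })
  data <- dplyr::bind_rows(lapply(sprintf("P%02d", 1:6), function(p) {
    transform(cell, participant_id = p)
  }))
  fit <- lmm_anova(data, "y", c("landmark", "condition"))
  expect_true(glance(fit)$singular)
  got <- tidy(fit)
  want <- oracle_fixed_anova(data, "y", c("landmark", "condition"))
  expect_equal(got$F[got$term == "landmark"],
               unname(want["landmark"]), tolerance = 1e-6)
  expect_equal(got$F[got$term == "condition"],
               unname(want["condition"]), tolerance = 1e-6)
  expect_equal(got$F[got$term == "landmark:condition"],
               unname(want["landmark:condition"]), tolerance = 1e-6)
})

test_that("lmm_anova keeps all observations under unbalanced dropout", {
  cfg <- cohort_config(
    n_participants = 7,
    dropout_pattern = c(rep("both", 5), "semi_only", "semi_only"),
    encoding_duration = tibble::tibble(condition = condition_levels(),
                                       mean = 0.02, sd = 0),
    recall_duration = tibble::tibble(condition = condition_levels(),
                                     mean = 0.02, sd = 0),
    seed = 45L)
  trials <- polar_error(simulate_cohort(cfg)$trials)
  expect_identical(nrow(trials), 192L) # 5 x 2 x 16 + 2 x 16
  fit <- lmm_anova(trials, "r", c("landmark", "condition"))
  expect_identical(glance(fit)$n_obs, 192L)
  expect_identical(glance(fit)$n_participants, 7L)
  expect_identical(tidy(fit)$term,
                   c("landmark", "condition", "landmark:condition"))
  expect_true(all(tidy(fit)$F >= 0))
})

test_that("lmm_anova is invariant to row order and level relabeling", {
  trials <- polar_error(fixture_cohort()$trials)
  base <- tidy(lmm_anova(trials, "r", c("landmark", "condition")))
  withr::with_seed(46, shuffled <- trials[sample(nrow(trials)), ])
  expect_equal(tidy(lmm_anova(shuffled, "r", c("landmark", "condition"))),
               base, tolerance = 1e-8)
  relab <- dplyr::mutate(
    trials,
    landmark = ifelse(landmark == "allocentric", "zz_world", "aa_body"))
  relab_tab <- tidy(lmm_anova(relab, "r", c("landmark", "condition")))
  expect_equal(relab_tab$F, base$F, tolerance = 1e-8)
})

test_that("a single-level factor raises a model error naming the factor", {
  trials <- polar_error(fixture_cohort()$trials)
  only_imm <- dplyr::filter(trials, condition == "immersive")
  expect_error(lmm_anova(only_imm, "r", c("landmark", "condition")),
               class = "navassess_model_error", regexp = "condition")
})

test_that("injecting a condition effect raises the rejection rate above null", {
  design <- expand.grid(landmark = c("allocentric", "egocentric"),
                        condition = c("immersive", "semi_immersive"),
                        trial = 1:4,
                        participant_id = sprintf("P%02d", 1:7),
                        stringsAsFactors = FALSE)
  run <- function(effect, seed) {
    withr::with_seed(seed, {
      mean(vapply(1:100, function(i) {
        d <- design
        ints <- rnorm(7, 0, 0.5)
        d$y <- ints[match(d$participant_id, sprintf("P%02d", 1:7))] +
          rnorm(nrow(d)) + effect * (d$condition == "immersive")
        tab <- tidy(lmm_anova(d, "y", c("landmark", "condition")))
        tab$p[tab$term == "condition"] < 0.05
      }, logical(1)))
    })
  }
  null_rate <- run(0, 71)
  power_rate <- run(1, 72) # 1 residual-SD condition effect
  expect_gt(power_rate, null_rate)
  expect_gt(power_rate, 0.5)
})
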