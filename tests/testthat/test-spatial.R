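# Polar recall-error metrics and cell summaries.

test_that("polar_error reproduces hand geometry", {
  pe <- polar_error(toy_trials())
  # 3-4-5 triangle from the origin
  expect_equal(pe$r[1], 5)
  expect_equal(pe$theta_deg[1], atan2(4, 3) * 180 / pi)
  # pure -x displacement of length 6
  expect_equal(pe$r[2], 6)
  expect_equal(pe$theta_deg[2], 180)
  # zero displacement: r = 0, angle undefined
  expect_equal(pe$r[3], 0)
  expect_true(is.na(pe$theta_deg[3]))
  # pure +z displacement
  expect_equal(pe$theta_deg[4], 90)
})

test_that("the angle-direction flag flips theta by 180 degrees", {
  pe_fwd <- polar_error(toy_trials())
  pe_rev <- polar_error(toy_trials(), angle_direction = "recall_to_encoding")
  expect_equal(pe_rev$r, pe_fwd$r)
  ok <- !is.na(pe_fwd$theta_deg)
  expect_equal(pe_rev$theta_deg[ok], (pe_fwd$theta_deg[ok] + 180) %% 360)
})

test_that("r is rigid-motion invariant and theta rotation-equivariant", {
  withr::with_seed(21, {
    trials <- tibble::tibble(
      enc_x = rnorm(50), enc_z = rnorm(50),
      rec_x = rnorm(50), rec_z = rnorm(50))
    base <- polar_error(trials)
    for (ang in c(30, 117, 270)) {
      a <- ang * pi / 180
      rot <- function(x, z) list(x = cos(a) * x - sin(a) * z,
                                 z = sin(a) * x + cos(a) * z)
      e <- rot(trials$enc_x, trials$enc_z)
      r <- rot(trials$rec_x, trials$rec_z)
      moved <- polar_error(tibble::tibble(
        enc_x = e$x + 5, enc_z = e$z - 3,
        rec_x = r$x + 5, rec_z = r$z - 3))
      expect_equal(moved$r, base$r, tolerance = 1e-12)
      diff <- (moved$theta_deg - base$theta_deg) %% 360
      expect_equal(diff, rep(ang, 50), tolerance = 1e-8)
    }
  })
})

test_that("non-finite coordinates raise an input error", {
  bad <- toy_trials()
  bad$rec_x[1] <- Inf
  expect_error(polar_error(bad), class = "navassess_input_error")
})

test_that("classify_recall includes the boundary and is monotone in r", {
  trials <- tibble::tibble(enc_x = 0, enc_z = 0,
                           rec_x = c(0, 6, 6.0001, 3), rec_z = 0)
  cl <- classify_recall(trials)
  expect_identical(cl$correct, c(TRUE, TRUE, FALSE, TRUE))
  # monotone non-increasing in r over a sweep
  sweep <- classify_recall(tibble::tibble(
    enc_x = 0, enc_z = 0, rec_x = seq(0, 12, by = 0.5), rec_z = 0))
  expect_true(all(diff(as.integer(sweep$correct)) <= 0))
  expect_error(classify_recall(trials, radius = -1),
               class = "navassess_input_error")
})

test_that("summarize_errors matches hand arithmetic and the loop oracle", {
  # two trials with r = 3 and 5 in one cell
  two <- tibble::tibble(
    landmark = "allocentric", condition = "immersive",
    enc_x = 0, enc_z = 0, rec_x = c(3, 5), rec_z = 0)
  s <- summarize_errors(two)
  expect_equal(s$mean_r, 4)
  expect_equal(s$sd_r, sqrt(2))

  # empty input -> empty summary
  expect_identical(nrow(summarize_errors(two[0, ])), 0L)

  # full fixture vs naive loop oracle, exact
  trials <- fixture_cohort()$trials
  got <- as.data.frame(summarize_errors(trials))
  want <- oracle_summarize_errors(trials)
  got <- got[order(got$landmark, got$condition), ]
  want <- want[order(want$landmark, want$condition), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("r = 0 trials enter distance but not angle aggregates", {
  mix <- tibble::tibble(
    landmark = "egocentric", condition = "immersive",
    enc_x = 0, enc_z = 0, rec_x = c(0, 4), rec_z = c(0, 0))
  s <- summarize_errors(mix)
  expect_identical(s$n_trials, 2L)
  expect_identical(s$n_theta, 1L)
  expect_equal(s$mean_r, 2)
  expect_equal(s$mean_theta, 0)
})

test_that("the circular-mean variant agrees at concentrated angles and wraps", {
  wrap <- tibble::tibble(
    landmark = "allocentric", condition = "immersive",
    enc_x = 0, enc_z = 0,
    rec_x = c(cos(-pi / 36), cos(pi / 36)),
    rec_z = c(sin(-pi / 36), sin(pi / 36))) # 355 and 5 degrees
  lin <- summarize_errors(wrap)
  circ <- summarize_errors(wrap, circular = TRUE)
  expect_equal(lin$mean_theta, 180) # arithmetic mean straddles the wrap
  ang_dist <- min(circ$mean_theta %% 360, 360 - circ$mean_theta %% 360)
  expect_lt(ang_dist, 1e-8)
})
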