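# Within-subject group statistics: paired t, Wilcoxon signed-rank with
# tie diagnostics, and trial-level mixed-effects ANOVA with participant
# random intercepts.

new_nav_test <- function(method, statistic, df, p, n_pairs, tied_pairs,
                         estimate) {
  structure(list(method = method, statistic = statistic, df = df, p = p,
                 n_pairs = n_pairs, tied_pairs = tied_pairs,
                 estimate = estimate),
            class = "nav_test")
}

#' @export
print.nav_test <- function(x, ...) {
  lab <- c(paired_t = "Paired t-test",
           wilcoxon_signed_rank = "Wilcoxon signed-rank test")[x$method]
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (n = %d pairs, %d tied)\n",
              lab, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p, x$n_pairs, x$tied_pairs))
  invisible(x)
}

#' @export
tidy.nav_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, df = x$df, p = x$p,
         n_pairs = x$n_pairs, tied_pairs = x$tied_pairs,
         estimate = x$estimate)
}

#' Paired Student's t-test
#'
#' Two-sided paired t-test on matched measurements: with differences
#' `d = x - y`, `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of
#' freedom. Pairs with a missing value in either member are dropped
#' first. A zero-variance difference vector (all differences equal) has
#' no defined t statistic and raises a degenerate-variance error.
#'
#' @param x,y numeric vectors of equal length (matched by position).
#' @return a `nav_test` object; see [tidy()] for its tabular form.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    input_error("Paired vectors must have equal length.")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2) input_error("Paired t-test needs at least 2 complete pairs.")
  d <- x - y
  if (sd(d) == 0) {
    abort("All paired differences are identical: the t statistic is undefined (zero variance).",
          class = "navassess_degenerate_error")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  new_nav_test("paired_t", unname(ht$statistic), unname(ht$parameter),
               ht$p.value, n, sum(d == 0), mean(d))
}

#' Wilcoxon signed-rank test
#'
#' Paired Wilcoxon signed-rank test with the W = "sum of positive-rank"
#' convention: pairs with zero difference are dropped and their count
#' reported as `tied_pairs`; the remaining absolute differences are
#' ranked and W sums the ranks of the positive differences (so W = 0
#' when y exceeds x in every untied pair). The two-sided p-value is
#' exact for up to 25 untied pairs without tied ranks, and a normal
#' approximation with tie correction otherwise.
#'
#' @inheritParams paired_t
#' @return a `nav_test` object (`df` is NA).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) {
    input_error("Paired vectors must have equal length.")
  }
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  n_pairs <- length(d)
  tied <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n < 1) {
    input_error("Wilcoxon signed-rank needs at least one nonzero difference.")
  }
  ranks <- rank(abs(d))
  w <- sum(ranks[d > 0])
  exact <- n <= 25 && !any(duplicated(ranks))
  ht <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = !exact)
  )
  new_nav_test("wilcoxon_signed_rank", w, NA_real_, ht$p.value, n_pairs,
               tied, stats::median(d))
}

#' Compare conditions within subjects
#'
#' Runs the paired Student's t and the Wilcoxon signed-rank test side by
#' side (the two are always reported together) on a per-participant
#' measurement taken under both conditions. Participants lacking either
#' condition are dropped pairwise.
#'
#' @param data data frame with one row per participant x condition.
#' @param value name (string) of the measurement column.
#' @param condition,participant names of the condition and participant
#'   columns (defaults `"condition"`, `"participant_id"`). The first
#'   condition level (alphabetical, or factor order) plays the role of
#'   `x`, the second of `y`, so a negative t means the first-level values
#'   are lower.
#' @return tibble with one row per test: `method`, `statistic`, `df`,
#'   `p`, `n_pairs`, `tied_pairs`, `estimate`.
#' @export
compare_conditions <- function(data, value, condition = "condition",
                               participant = "participant_id") {
  assert_cols(data, c(value, condition, participant), "data")
  lv <- if (is.factor(data[[condition]])) levels(data[[condition]])
        else sort(unique(data[[condition]]))
  if (length(lv) != 2) {
    input_error("`compare_conditions()` needs exactly 2 condition levels.")
  }
  wide <- data |>
    select(dplyr::all_of(c(participant, condition, value))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(condition),
                       values_from = dplyr::all_of(value))
  x <- wide[[lv[1]]]
  y <- wide[[lv[2]]]
  bind_rows(tidy(paired_t(x, y)), tidy(wilcoxon_signed_rank(x, y)))
}

#' Mixed-effects ANOVA with participant random intercepts
#'
#' Fits `response ~ factor_a * factor_b + (1 | participant)` by REML and
#' returns the type-III F table with Satterthwaite denominator degrees
#' of freedom (sum-to-zero contrasts). Working at the trial level, the
#' model keeps every observation: participants missing a condition
#' contribute their remaining trials instead of being dropped, which is
#' why the denominator df tracks the trial count rather than the
#' participant count. A random-intercept variance estimated at the
#' boundary (zero) is reported via `glance()`, not treated as an error.
#'
#' @param data long-format data frame, one row per observation.
#' @param response name (string) of the response column.
#' @param fixed character vector of two fixed-factor column names.
#' @param participant name of the grouping column (default
#'   `"participant_id"`).
#' @return an object of class `nav_anova`; `tidy()` gives the F table
#'   (term, F, num_df, den_df, p), `glance()` the fit diagnostics.
#' @export
lmm_anova <- function(data, response, fixed, participant = "participant_id") {
  assert_cols(data, c(response, fixed, participant), "data")
  if (length(fixed) != 2) {
    input_error("`fixed` must name exactly two factors.")
  }
  data <- as.data.frame(data)[c(response, fixed, participant)]
  data <- data[stats::complete.cases(data), , drop = FALSE]
  for (f in c(fixed, participant)) data[[f]] <- factor(data[[f]])
  for (f in fixed) {
    lvl <- levels(droplevels(data[[f]]))
    if (length(lvl) < 2) {
      abort(sprintf("Factor `%s` has fewer than 2 observed levels (found: %s).",
                    f, paste(lvl, collapse = ", ")),
            class = "navassess_model_error")
    }
    stats::contrasts(data[[f]]) <- stats::contr.sum(length(lvl))
  }
  if (length(unique(data[[participant]])) < 2) {
    input_error("Mixed-effects ANOVA needs at least 2 participants.")
  }
  fml <- stats::as.formula(sprintf("`%s` ~ `%s` * `%s` + (1 | `%s`)",
                                   response, fixed[1], fixed[2], participant))
  fit <- suppressMessages(
    lmerTest::lmer(fml, data = data, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     optCtrl = list(xtol_abs = 1e-8, ftol_abs = 1e-8)))
  )
  tab <- suppressMessages(anova(fit, type = 3, ddf = "Satterthwaite"))
  terms <- rownames(tab)
  structure(list(
    table = tibble(term = gsub("`", "", terms),
                   F = tab[["F value"]],
                   num_df = as.integer(tab[["NumDF"]]),
                   den_df = tab[["DenDF"]],
                   p = tab[["Pr(>F)"]]),
    fit = fit,
    n_obs = nrow(data),
    n_participants = length(unique(data[[participant]])),
    response = response
  ), class = "nav_anova")
}

#' @export
print.nav_anova <- function(x, ...) {
  cat(sprintf(
    "Mixed-effects ANOVA on `%s` (%d observations, %d participants)\n",
    x$response, x$n_obs, x$n_participants))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
tidy.nav_anova <- function(x, ...) x$table

#' @export
glance.nav_anova <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$fit))
  tibble(n_obs = x$n_obs,
         n_participants = x$n_participants,
         participant_sd = vc$sdcor[vc$grp != "Residual"][1],
         residual_sd = vc$sdcor[vc$grp == "Residual"][1],
         singular = lme4::isSingular(x$fit),
         REMLcrit = as.numeric(lme4::REMLcrit(x$fit)))
}
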