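# Independent brute-force oracles and a cached fixture cohort. The oracles
# are deliberately naive (loops, full enumeration, textbook formulas) and
# never call the implementation paths they check.

.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- reference_cohort()
  }
  .fixture_env$cohort
}

fixture_report <- function() {
  if (is.null(.fixture_env$report)) {
    .fixture_env$report <- run_pipeline(fixture_cohort())
  }
  .fixture_env$report
}

# Textbook paired t: t = mean(d) / (sd(d)/sqrt(n)), df = n - 1.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1))
}

# Exact Wilcoxon signed-rank two-sided p by enumeration over all 2^n sign
# assignments of the ranked absolute differences (zero diffs removed first).
oracle_wilcoxon_exact <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% ranks
  mu <- n * (n + 1) / 4
  p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
  list(w = w_obs, p = min(1, p))
}

# Naive per-cell error summary: explicit loops, no dplyr.
oracle_summarize_errors <- function(trials) {
  dx <- trials$rec_x - trials$enc_x
  dz <- trials$rec_z - trials$enc_z
  r <- sqrt(dx^2 + dz^2)
  theta <- (atan2(dz, dx) * 180 / pi) %% 360
  theta[r == 0] <- NA
  out <- NULL
  for (lm in sort(unique(trials$landmark))) {
    for (cond in sort(unique(trials$condition))) {
      idx <- trials$landmark == lm & trials$condition == cond
      if (!any(idx)) next
      th <- theta[idx]
      th <- th[!is.na(th)]
      out <- rbind(out, data.frame(
        landmark = lm, condition = cond, n_trials = sum(idx),
        mean_r = mean(r[idx]), sd_r = sd(r[idx]), n_theta = length(th),
        mean_theta = if (length(th)) mean(th) else NA_real_,
        sd_theta = if (length(th)) sd(th) else NA_real_))
    }
  }
  out
}

# Classic two-way fixed-effects ANOVA F statistics via aov() with
# sum-to-zero contrasts (balanced designs).
oracle_fixed_anova <- function(data, response, fixed) {
  for (f in fixed) {
    data[[f]] <- factor(data[[f]])
    contrasts(data[[f]]) <- contr.sum(nlevels(data[[f]]))
  }
  fml <- as.formula(paste(response, "~", fixed[1], "*", fixed[2]))
  tab <- summary(aov(fml, data = data))[[1]]
  fs <- tab[["F value"]]
  names(fs) <- trimws(rownames(tab))
  fs[!is.na(fs)]
}

# A small deterministic trial table with hand-checkable geometry.
toy_trials <- function() {
  tibble::tibble(
    participant_id = "P01",
    condition = rep(c("immersive", "semi_immersive"), each = 2),
    landmark = "allocentric",
    item_id = c(1L, 2L, 1L, 2L),
    repetition = 1L,
    enc_x = c(0, 10, 0, 1),
    enc_z = c(0, 10, 0, 1),
    rec_x = c(3, 4, 0, 1),
    rec_z = c(4, 10, 0, 4),
    recall_latency = 5
  )
}
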