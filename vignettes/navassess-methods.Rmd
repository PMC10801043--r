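---
title: "Methods: spatial-memory, motion and usability analytics in navassess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-memory, motion and usability analytics in navassess}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navassess)
```

`navassess` analyses seated VR object-relocation tasks: participants first
visit four object locations along a guided path (encoding), then replace each
object from memory (recall), navigating with a foot-motion pad whose pitch
(toe–heel) and yaw (left–right) tilts drive translation and rotation. Each
participant attempts the task under an immersive (head-mounted display) and
a semi-immersive (large monitor) condition, and each recall block is run with
one of two landmark configurations intended to force an allocentric
(world-centred) or egocentric (body-centred) strategy. This vignette
documents the statistical models, the defaults and their rationale, what the
synthetic cohort generator does and does not emulate, and the numerical
choices a careful reader should know about.

## Recall error in polar coordinates

For a trial with encoding location $(x_e, z_e)$ and recalled location
$(x_r, z_r)$ on the environment's horizontal plane, the displacement is
expressed in polar coordinates centred on the item:

$$ r = \sqrt{(x_r - x_e)^2 + (z_r - z_e)^2}, \qquad
   \theta = \operatorname{atan2}(z_r - z_e,\, x_r - x_e) \bmod 360^\circ . $$

$r$ (virtual units) answers *how far* the response was from the item;
$\theta$ (degrees) *at what angle*. Conventions we fixed where the task
itself leaves them open:

- **Angle reference.** $\theta$ is measured from the environment's $+x$
  axis, counter-clockwise, in $[0^\circ, 360^\circ)$. Since $\theta$ is
  rotation-equivariant, only internal consistency matters; the reference
  axis is a label, not a claim about the environment.
- **Angle direction.** The displacement is taken encoding → recall by
  default; `polar_error(..., angle_direction = "recall_to_encoding")` flips
  every defined angle by exactly 180°. The two conventions are
  information-equivalent; we expose both because either reading of "angle of
  the response relative to the item" is defensible.
- **Degenerate trials.** When $r = 0$ the angle is undefined and stored as
  `NA`; such trials enter distance aggregates but are excluded from angle
  aggregates (`n_theta` counts the contributors).
- **Correctness.** A recall is correct when $r \le 6$ virtual units,
  boundary inclusive; the radius is a `cohort_config()` /
  `classify_recall()` parameter.

Cell summaries use the sample SD ($n-1$), the standard choice for
small-cohort reporting. Angles are averaged **arithmetically on degree
values** by default. This is deliberate: with errors widely dispersed around
the item, degree values near 0 and near 360 both occur, the arithmetic mean
gravitates toward 180°, and large SDs (around 100° here) follow — which is
how such tables are commonly reported. The statistically conventional
alternative (circular mean, and circular SD $\sqrt{-2\ln \bar R}$) is
available via `summarize_errors(..., circular = TRUE)`; the two differ
materially exactly when the angle distribution is diffuse, so reporting
should name the variant used.

## Inference: paired tests and the mixed-effects ANOVA

Condition contrasts on participant-level scores (SUS, ITC-SOPI-NE, Jaccard,
encoding time) always report the paired Student's t **and** the Wilcoxon
signed-rank test together. The Wilcoxon statistic is the positive-rank sum
$W$: zero differences are dropped before ranking and their count surfaced as
`tied_pairs`, so $W = 0$ states that the second condition was rated at least
as high by every untied pair. The two-sided p-value is exact (via the null
distribution of $W$) for $\le 25$ untied pairs without tied ranks, and a
normal approximation with tie correction otherwise. These wrap
`stats::t.test()` and `stats::wilcox.test()`; the test suite checks them
against a textbook-formula recomputation and a full $2^n$ sign-enumeration
oracle, which are kept independent of the wrapped calls.

Trial-level inference fits

$$ y_{ijkt} = \mu + \alpha_i + \beta_j + (\alpha\beta)_{ij} + u_k +
   \varepsilon_{ijkt}, \qquad u_k \sim N(0, \sigma_u^2), $$

with landmark $i$, condition $j$, participant $k$, by REML
(`lmerTest::lmer`), reporting type-III F statistics with Satterthwaite
denominator df under sum-to-zero contrasts. Because the model works on
trials rather than participant means, a participant who completed only one
condition still contributes all their trials, and the denominator df tracks
the trial count (around 170 for an 11-session cohort) rather than the
participant count. Numerical choices: optimizer tolerances $10^{-8}$
(absolute, on parameters and objective); a random-intercept variance
estimated at the boundary ($\hat\sigma_u^2 = 0$) is legitimate — it is
reported through `glance()` (`singular = TRUE`), not raised as an error. In
that degenerate limit the F statistics coincide with a classic two-way
fixed-effects ANOVA, which the tests verify to $10^{-6}$.

Movement magnitude is analysed at the **phase level**: $v_t$ is averaged per
(participant, condition, phase) before the phase × condition mixed ANOVA.
The session-log format does not segment motion traces by trial, so a
trial-level magnitude response is not representable; phase averages are the
finest response the data model supports, and with 11 sessions they yield the
small denominator df (around 10–15) characteristic of participant-level
analyses.

## Foot-motion analytics

Each pad sample reduces to $v_t = \sqrt{y_t^2 + z_t^2}$ — zero iff the pad
is neutral, larger with greater lower-limb mobility; the reduction is
invariant under a joint sign flip of both tilts.

**Encoding–recall similarity.** A set-theoretic Jaccard index is not
directly computable on two continuous, different-length series, so the
package uses the standard continuous generalization: histogram both
magnitude series over shared bins of width `bin_width` on $[0, \max v]$,
normalize to relative frequencies $p, q$, and report

$$ J = \frac{\sum_b \min(p_b, q_b)}{\sum_b \max(p_b, q_b)} \in [0, 1], $$

which reproduces the anchor cases (identical profiles → 1, disjoint
supports → 0), is symmetric, and is invariant to duplicating every sample —
hence robust to encoding lasting longer than recall. Default
`bin_width = 0.05` magnitude units: tilts live in $[-1, 1]$, so magnitudes
rarely exceed $\sqrt 2$, and 0.05 gives roughly 20–30 occupied bins —
fine enough to separate movement regimes, coarse enough that bins are well
populated at 100 Hz. Because the right variant is genuinely underdetermined
(raw counts, binarized occupancy and normalized frequencies all reproduce
the 1/0 anchors), all three are implemented and labelled
(`method = "weighted" / "counts" / "binary"`); `"weighted"` is the default
for its length-robustness.

**Density grids.** Raw $(y, z)$ samples are counted in square cells of side
0.1 tilt units — the tabular counterpart of a hexagonal-density plot;
squares preserve the analytical content (counts per cell, conservation of
the sample total) while keeping the grid exportable as a plain table.

**Durations.** A trace's phase duration is its timestamp span,
$(t_{\max} - t_{\min})/60000$ minutes; the validator flags sampling gaps
exceeding twice the nominal 10 ms interval, and checks stored durations
against trace extents within 0.02 min.

## Questionnaire scoring

SUS: 10 items on 1–5 Likert; odd items contribute `response − 1`, even items
`5 − response`; the sum × 2.5 gives 0–100 in steps of 2.5. The adjective
bands are applied as half-open intervals — worst imaginable $[0, 26)$, awful
$[26, 40)$, poor $[40, 50)$, OK $[50, 70)$, good $[70, 85)$, excellent
$[85, 100)$, best imaginable $\{100\}$ — because the conventional printed
integer ranges leave fractional scores (e.g. 69.5) ambiguous; half-open
edges assign every representable score to exactly one band, which the tests
verify by exhaustive sweep. ITC-SOPI negative effects: the mean of completed
items only; the scorer is length-agnostic because the instrument's item list
is licensed content the package does not embed.

## The synthetic cohort generator

The generator exists so every downstream stage can be tested against known
ground truth. Its defaults are the study conditions the package targets:

| parameter | default | rationale |
|---|---|---|
| participants | 7; 5 complete both, 1 semi-only, 1 none | realistic usability-cohort size with cybersickness dropouts; yields 11 sessions / 176 trials |
| task structure | 4 items × 4 repetitions; 2 allocentric + 2 egocentric recall blocks in random order | mirrors the protocol; balanced blocks guarantee both factor levels per session, which the ANOVA requires |
| recall displacement | isotropic bivariate Gaussian, per-cell $\sigma$ ≈ 16.4–21.1 vu | $\sigma$ recovered from target cell mean errors via the Rayleigh relation (below) |
| correctness radius | 6 vu | the task's feedback rule |
| motion model | AR(1)/OU: rate 2 s⁻¹, volatility 0.53 s^−1/2^, clip 1 | bounded tilt that wanders around neutral; stationary per-axis SD ≈ 0.27 puts the mean magnitude near 0.33 |
| durations | encoding 10.3 (SD 3.21) / 8.51 (SD 2.29) min by condition; recall 6 (SD 2) min | encoding targets from the study conditions; recall durations are unreported, so a plausible value was fixed once |
| questionnaires | SUS 65 (22.97) / 69.17 (25.52); ITC-NE 2.03 (0.91) / 1.53 (0.56); 6 NE items | instrument targets per condition |

**Why an isotropic Gaussian displacement?** It is the simplest model with a
closed-form error law: $r \sim \mathrm{Rayleigh}(\sigma)$, so
$\mathbb E[r] = \sigma\sqrt{\pi/2}$, the correct-recall probability is
$1 - e^{-6^2/(2\sigma^2)}$, and $\theta$ is exactly uniform. These three
facts are the acceptance-grade parameter-recovery tests (mean within 2% at
≥ 10,000 trials; correctness within binomial bounds; $\chi^2$ uniformity on
36 bins at $\alpha = 0.001$).

**Motion traces** are discrete mean-reverting processes per axis,
$x_{t+1} = (1 - \kappa\,\Delta t)\,x_t + \sigma_v \sqrt{\Delta t}\,
\varepsilon_t$, with the emitted sample saturated at $\pm$`clip`. The
saturation is applied to the output, not fed back into the recursion — at
the default parameters the process sits at ≈ 3.8 stationary SDs from the
bound, so saturation is rare and the distinction immaterial; it buys a fully
vectorized simulation. Traces have exactly `round(duration × 6000)` samples
at 10 ms spacing.

**Questionnaire responses** come from a participant-level latent Gaussian at
the instrument target (clamped to the scale), plus item-level noise, rounded
and clamped into 1–5. Means land near targets; the clamping and rounding
bias them slightly toward the scale interior, which the generator does not
correct for — the targets parameterize intent, not a guaranteed moment.

**Reproducibility.** One root seed; each (participant, condition, purpose)
stream derives its own substream seed through a fixed affine hash modulo
$2^{31}-1$ (`substream_seed()`), so enlarging the cohort regenerates earlier
participants bit-identically — a property the tests assert.

**What the generator does not emulate.** Real pad telemetry is
task-entrained (bursts of travel between items, idle periods during search);
the OU model is stationary, so encoding and recall magnitude distributions
are nearly identical and the synthetic Jaccard indices run high (≈ 0.7–0.95)
compared with what heterogeneous human sessions produce. Recall
displacements are independent across trials, with no learning, fatigue,
spatial bias toward the arena centre, or item-specific difficulty; angle
uniformity is an assumption of the noise model, not a behavioural claim.
Passing parameter-recovery tests therefore shows the *pipeline* is correct,
not that real data will exhibit these distributions.

## Problem sizes and runtime choices

The reference fixture (`reference_cohort()`) is the 7-participant study
layout with shortened motion traces (0.1–0.25 min per phase), keeping the
default test run light while preserving every structural property.
Closed-form recovery tests use 320 two-condition participants (10,240
trials) with 0.02 min traces; the ANOVA calibration uses 200 null replicates
(and 100 per arm for the power smoke test) of a 7 × 2 × 2 × 4 design. The
acceptance script runs the full-duration default cohort (≈ 1.2 million
motion samples) in a few seconds.

## Known limitations

- The deposited-archive importer (`import_deposited()`) handles only the
  package's own directory layout; adapting a specific external archive
  requires inspecting it, which the adapter surfaces as a typed error
  listing the files found.
- Arithmetic angle means are reference-frame-dependent for diffuse
  distributions; use the circular variant for directional inference.
- The Jaccard index compares magnitude *distributions*; it carries no
  information about temporal alignment of movements within a phase.
- With 5–7 pairs, the paired tests have little power and the Wilcoxon exact
  p has a coarse support; significance statements at this scale are
  descriptive, not confirmatory.
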