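---
title: "Methods: simulating and analyzing automatic behavior shaping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing automatic behavior shaping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapesim)
```

## The task and the shaping-function family

`shapesim` models an automatic behavior-shaping experiment. A hidden
*target circle* (radius 100 px) sits at a random location on a blank
1920 x 1080 screen; a concentric *reinforcement circle* (initially 400 px)
defines the set of clicks that earn a reward. Each reward contracts the
reinforcement circle toward the target according to a shaping schedule

$$
r(n) \;=\; r_0 \;-\; (r_0 - r_T)\,\frac{1 - e^{bn}}{1 - e^{b\,n_{\max}}},
\qquad 0 \le n \le n_{\max},
$$

where $n$ counts reinforcements so far, $r_0 = 400$, $r_T = 100$ and
$n_{\max} = 10$. The contraction rate $b$ sets the schedule's shape:
$b < 0$ is concave-up (rapid early narrowing), $b > 0$ concave-down (slow
early narrowing), and the $b \to 0$ limit is the straight line
$r(n) = -30n + 400$. The exponential form is singular at $b = 0$, so
`shaping_radius()` dispatches to the closed linear form when
$|b| < 10^{-8}$; at $|b| = 10^{-8}$ the two forms differ by far less than
numerical noise on a pixel scale. Reinforcement counts above $n_{\max}$
are clamped — the window is held at the target radius for the remainder of
the trial — rather than rejected, since the task itself never un-contracts.
The three experimental arms are `shaping_presets()`: $b = -0.3$
(concave-up), $b = 0$ (linear), $b = 0.3$ (concave-down).

A trial consists of up to 50 clicks and ends early once 10 consecutive
clicks land inside the target circle. A click is judged against the radius
in force *before* it: a reinforced click's contraction applies from the
next click onward. "Inside" means a closed disk
(distance $\le$ radius) for both circles; the boundary is a measure-zero
set, but scripted tests need a fixed convention. Clicks are real-valued
coordinates: the synthetic agents are continuous samplers, and integer
pixel truncation would only add unmodeled noise. Target clicks are
reinforced clicks, so they also advance the contraction count.

## Synthetic participants

No behavioral model of the human participants is available, so the cohort
generator is an invention of this package, built to have the minimal
structure the analysis layer assumes: reinforcement history must causally
matter, and participants must differ stably from one another.

The default agent is a *win-stay/shift* searcher
(`agent_win_stay_shift()`). Before its first reinforcement it explores
uniformly. After a reinforced click it re-centers its search on that
location and samples an isotropic Gaussian around it, multiplying its
spread by `shrink`; after a non-reinforced click it returns to the last
reinforced location and widens its spread by `grow` (capped). With
probability `lapse` a click is replaced by a uniform off-policy click.
Off-screen draws are rejected and redrawn rather than clamped, so no
probability mass piles up on the screen edges. This mechanism makes the
shaping schedule consequential: a rapidly contracting (concave-up) window
only rewards clicks near the target, so the searcher's anchor is dragged
onto the target early, while a slowly contracting (concave-down) window
keeps rewarding distant clicks and entrenches the search far from the
target.

Cohorts come from `make_cohort()`: each participant's `sigma_exploit` is
perturbed log-normally and their `lapse` logit-normally with standard
deviation `skill_sd`, drawn once and fixed across that participant's 45
trials. This induces the nonzero between-participant variance component
that the mixed model partitions.

### Calibration of the defaults

The default parameters were fixed once by a seeded grid search
(`calibrate_agents()`, reproducible via the `calibrate` CLI subcommand)
over `sigma_exploit`, `shrink`, `grow` and `lapse`, scored on a reduced
cohort by whether mean AA is ordered concave-up > linear > concave-down
with mean total clicks reversed — the qualitative structure the task is
designed to produce — and by a nondegenerate spread of click counts. The
chosen defaults (`sigma_exploit = 250`, `shrink = 0.7`, `grow = 1.05`,
`lapse = 0.02`) sit in the interior of a broad region of parameter space
showing that ordering, and were frozen in
`inst/extdata/default-config.yaml`; they are study conditions, not tuning
knobs. The cohort heterogeneity `skill_sd = 0.6` was chosen separately so
that the between-participant differences are strong enough to register as
a nonzero random-intercept variance in the mixed model — the component the
variance partition exists to report — while leaving the arm ordering
untouched. The ordering they produce at the default cohort size is covered by
a seeded regression test.

What the generator does *not* emulate: systematic sweep-search strategies,
fatigue or practice effects across trials, breaks, reaction times, or any
learning of target locations across trials (targets are placed
independently every trial). The synthetic cohort is also weaker than a
human one — its mean click counts are higher and its accumulation areas
lower than the human-scale values — so passing tests demonstrate that the
pipeline detects the qualitative shaping structure, not that the agents
reproduce human effect magnitudes.

## Outcome measures

**Accumulation area (AA).** For each participant and shaping arm, every
trial's per-click target flags are expanded to the full 50 clicks: a trial
that ended early has its remaining clicks scored as target clicks, since
the participant had demonstrably located the target
(`target_flags()`). Flags are averaged across the arm's trials into an
empirical per-click probability-of-target trajectory, smoothed by loess,
and integrated (`accumulation_area()`). Higher AA means faster shaping.

Two conventions are deliberately pinned down where the smoother family
leaves them open. The loess smoother (`smooth_loess()`) uses local degree
2, the tricube kernel, span 0.4 interpreted as the nearest-neighbor
fraction (window of `ceiling(0.4 * 50) = 20` points), and no robustness
iterations — the conventional defaults for this smoother family; degree
and span are arguments, so the degree-1 reading is one keystroke away.
Fitted values are clamped to $[0, 1]$ before integration because local
polynomials can overshoot probabilities; a window too small to support the
local polynomial falls back to a single global polynomial fit. The AA
integral uses the trapezoid rule over unit-spaced click indices (maximum
49 for 50 clicks), which is consistent with AA magnitudes reported for
this task family on human data (around 29–34); a left Riemann sum
(maximum 50) is available behind the `rule` option.

**Total clicks.** The per-trial count of actual clicks only
(`clicks_table()`), between 10 and 50 by construction. Across a cohort it
is inversely — though not perfectly — correlated with AA, which is a
property-level check in the test suite.

## Inference layer

**AA model.** `fit_aa_model()` fits a random-intercept Gaussian mixed
model by REML (`lme4::lmer`): AA regressed on shaping function with a
per-participant intercept, linear as the referent level. Fixed-effect
intervals are Wald (normal approximation); the concave-down vs concave-up
comparison is obtained through a contrast vector on the fixed-effect
covariance matrix, so it equals the coefficient difference exactly.
Singular random-effects fits are flagged, never silently simplified.

**Variance partition.** `variance_partition()` reports the decomposition
three ways, because "proportion of variance due to X" is ambiguous for
mixed models: (i) the classical variance partition coefficient, between
-participant variance over (between + residual); (ii) shares of the
exhaustive total (fixed-effect predictor variance + between + residual),
which sum to 1; and (iii) a two-component reading normalizing the
between-participant and shaping-function components over their own sum,
which also sums to 1 but ignores the residual. All three are labelled in
the output rather than resolved silently, since published summaries of
this design have used a two-component summary whose exact estimator is
not stated.

**Clicks model.** `fit_clicks_model()` fits a negative-binomial
regression with log link (`MASS::glm.nb`) of per-trial clicks on shaping
function, without a hierarchical structure: in this design, a crossed
random-effects count model adds heavy machinery for random-effect
variance that is essentially zero (participants differ much less in raw
click counts than in AA, where trial noise has been averaged out), so the
plain GLM is the appropriate final model and the crossed NB GLMM is
deliberately not implemented. Effect sizes are incidence rate ratios
(exponentiated coefficients) with Wald intervals. As the overdispersion
diagnostic, the matching Poisson model's Pearson dispersion (sum of
squared Pearson residuals over residual degrees of freedom) is reported;
"dispersion parameter" has no unique estimator, and the Pearson form is
the standard choice for this diagnostic. `residual_diagnostics()` exports
normal quantile pairs and a kernel-density summary of the residuals for
the usual visual checks.

Parameter recovery for both models — bias and ~95% Wald interval coverage
— is verified by simulation in the test suite (200 replicates at the
experiment's own sample sizes: 54 participants for the mixed model, 810
trials per arm for the count model).

## Reproducibility and problem sizes

A master seed spawns one substream per participant covering target
placement, trial-order shuffling and agent noise, so a session replays
byte-identically from its configuration and seed; the CLI logs the seed
and a digest of the effective configuration with every run. The default
experiment (54 participants x 45 trials, up to 50 clicks each) simulates
in well under a minute; unit tests use reduced cohorts (3–12 participants)
chosen to exercise every code path while keeping the suite quick, and the
calibration search uses 12 participants x 6 trials per arm per candidate,
enough to rank candidates by their arm-mean gaps.

## Known limitations

- The agents are a minimal sufficient mechanism, not a cognitive model;
  their parameters were never fitted to human click data (none are
  public), and effect magnitudes on the synthetic cohort should not be
  compared numerically to human results.
- The trial-order shuffle is unconstrained and uniform; blocked or
  counterbalanced designs are not modeled.
- Breaks, fatigue and cross-trial learning are not modeled.
- AA is defined only per participant x arm (averaged over trials); a
  single trial's binary click outcomes do not support a trajectory, which
  is exactly why total clicks exists as the per-trial outcome.
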