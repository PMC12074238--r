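---
title: "Simulating performance accommodation mechanisms and analyzing ordinal ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating performance accommodation mechanisms and analyzing ordinal ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem pamsim addresses

Brain–computer interfaces used in motor-imagery stroke rehabilitation have
low and variable true-positive rates. Rehabilitation games built on such
input therefore confront players with failures they did not cause, which
erodes perceived control and can frustrate patients. One design response is
the *performance accommodation mechanism* (PAM): explicit, narratively
framed in-game help that either boosts successes or softens failures.

pamsim is a deterministic, agent-driven simulator of a blink-controlled
fishing game built around exactly this situation, together with the
measurement and ordinal mixed-model stack used to analyze it. It replaces
the human participant with a stochastic blink agent and the sensor with a
predefined recognition schedule, so every quantity of interest — the
session summary measures, the ordinal self-report models — can be
recomputed, audited, and extended without human subjects.

## The game model

A session consists of `n_trials` *reel trials* (default 20). A hooked fish
sits in one of `n_lanes` horizontal lanes, lane 1 being the top-most. In
each trial the player must blink once inside the trial window; the system,
however, recognizes blinks only in a predefined subset of trials.

**Schedule.** `build_trial_schedule()` fixes, before play, exactly
`round(success_rate * n_trials)` recognized trials (default 0.70, so 14 of
20), with the failure positions drawn by a seeded uniform permutation.
Rounding of rate-to-count conversions is half-away-from-zero throughout.
The success rate must be strictly below 1: the design guarantees every
player experiences system imprecision. A trial is *effectively* successful
only when it is scheduled for recognition **and** the agent produced at
least one in-range blink, so weak agents degrade sessions below the
scheduled rate, exactly as out-of-range or forgotten blinks did with the
sensor.

**Fish dynamics.** A successful trial reels the fish up one lane; from
lane 1 it is caught. A failed trial advances the fish's escape progress by
one (`UNREEL`); at `escape_threshold` failed trials (default 3) the fish
escapes (`LOSS`). Two readings of the escape rule are observationally
equivalent for all session measures: escape progress is *cumulative per
fish* by default, and an `escape_reset_on_success` flag provides the
consecutive-failures reading. The loss *replaces* the third unreel event —
this choice makes unreels plus losses add up exactly to the scheduled
failures in unassisted play, matching the printed condition tables.

**Help mechanisms.** Three PAMs, each designed to deliver up to
`help_rate` (default 0.30) help feedback:

* *Augmented success* (success-triggered): the fisherman reels two lanes
  instead of one. Under the `CONSTRAINED` activation rule help applies
  only when two full lanes can be reeled without catching; otherwise the
  trial degrades to an ordinary one-lane reel and the scheduled help flag
  is left unconsumed — which is why this variant's realized help feedback
  falls below the designed cap. The `REDESIGNED` rule also lets the boost
  complete a catch when the fish is within two lanes of the top, restoring
  the full cap.
* *Mitigated failure* (failure-triggered): a clamp freezes the fish's
  escape progress. The clamp is help feedback but **not** positive
  feedback — nothing was reeled.
* *Input override* (failure-triggered): a helper character performs the
  reel exactly as a player success would.

Failure-triggered help is scheduled on the first `round(help_rate *
n_trials)` unrecognized trials in trial order; success-triggered help
mirrors this on the first recognized trials. With the default 70/30 rates
the failure-triggered mechanisms therefore cover *every* scheduled
failure, which is what produces the zero-fish-lost columns of the
condition tables.

**What is abstracted.** The hook-movement subtask (arrow keys) is not
simulated: the agent always positions the hook before each reel trial. All
printed game measures concern the reel subtask only. Durations are
reported in simulated ticks (`trial_ticks = 5`, `rest_ticks = 2`,
`help_ticks = 3` per consumed help), not wall-clock seconds; the tick
constants are arbitrary units and only their bookkeeping is tested.

**Lane geometry.** The lane count and spawn distribution are free
parameters of the design; the defaults (3 lanes, spawns uniform over lanes
2–3, never the top lane) put the mean reels-per-catch at 2.5, which makes
a 14-positive reference session yield about 5.3 catches — consistent with
the printed reference-condition tallies. A fish can spawn in any
configured lane except the top one, since a top-lane spawn would need zero
reel-ups before the catch attempt.

One known discrepancy is documented rather than modeled: in the original
stroke-patient deployment the constrained augmented-success rule appears
to have *discarded* successful input entirely when the boost could not
activate (its positive feedback column sits far below the scheduled rate),
whereas pamsim degrades such trials to an ordinary reel and only the help
feedback is depressed. The degrade reading keeps positive feedback at the
scheduled success rate, which is the behavior of the redesigned variant's
study and the contract the simulator tests.

## Agents

An `agent_profile()` has three knobs: `compliance_probability` (does the
agent blink at all in a trial window), a `1 + Poisson(lambda)` blink count
on compliant trials (players blink one or more times per attempt),
truncated at `max_blinks`, and `in_range_probability` (at least one blink
lands inside the tracker's range, an independent per-trial Bernoulli —
temporal drift in posture is deliberately out of scope). Expected per-trial
recognition is the product `compliance * in_range`.

The presets encode the two cohorts:

* `study1_patient`: recognition 0.88 split as compliance 0.95 times
  in-range 0.926, mean 2.1 blinks per trial. The split between forgetting
  and leaning is not separately identified by the published summary
  statistics, so both knobs are exposed rather than guessed at.
* `study2_gamer`: compliance 1, in-range 0.99, mean about 2.7 blinks per
  trial; the blink mean is set so the reference-condition blink conversion
  lands near the published 26%.
* `ideal` and `absent` bound the range (recognition 1 and 0).

## Session measures

`compute_session_measures()` reproduces the published measure definitions:
blink recognition (fraction of trials containing an in-range blink;
superfluous blinks in failed trials ignored), blink conversion (player
reel and catch events over all blinks — catches count, since the catch is
the final reel; help-driven reels do not, as no blink of the player caused
them), positive feedback (fraction of trials ending in any reel or catch),
help rate (fraction of trials with help feedback), and the four fish
counts. Two documented edge cases: conversion is defined as 0 when a
session contains no blinks at all, and the intuitive bound
`conversion <= recognition` is only guaranteed for agents that blink at
least once per trial (a non-compliant agent can produce fewer blinks than
trials, making the ratio's denominators incomparable); the property test
covers the always-blinking case.

`flag_recognition_anomalies()` implements the screening rule that dropped
participants whose sessions showed no blink recognition at all (threshold
0, configurable). `prep_violin_data()` performs the purely visual
normalize-to-0–1-and-jitter-by-2% transform used for violin plots;
analysis always treats ratings as ordinal.

## Synthetic ordinal ratings

`generate_ratings()` inverts the analysis model: for participant *i* a
random intercept `u_i ~ N(0, sd^2)` is drawn, and each rating is drawn
from `P(Y <= j) = logistic(theta_j - x'beta - u_i)` on the seven-point
scale. The default specifications carry the published fitted effects:
perceived control rises 0.61 log-odds per fish reeled with intercept SD
2.31; frustration falls 0.24 per fish reeled and rises 0.37 per fish lost.
The frustration model's intercept SD was not published; the default of 1.5
is a mid-range choice fixed once. Coefficients apply to *raw* counts — the
per-fish interpretation of the published effects implies raw units, so no
standardization is applied.

Cutpoints were likewise not published. By default six equally spaced
cutpoints (spacing 1) are centered on the covariate-mean linear predictor
at generation time, which keeps the generated ratings non-degenerate
across the covariate ranges the game actually produces; any fixed cutpoint
vector can be supplied instead.

## The cumulative link mixed model

`fit_clmm()` maximizes the Laplace-approximated marginal likelihood of the
proportional-odds model with a Gaussian participant intercept. Choices
that matter:

* **Parameterization.** No separate fixed intercept — it is absorbed into
  the cutpoints (the standard cumulative-link identification). Internally
  the cutpoints are (first cutpoint, log-spacings) so they stay strictly
  increasing, and the intercept SD is optimized on the log scale to stay
  positive.
* **Laplace step.** Each participant's integral is approximated by a
  second-order expansion around the conditional mode of the intercept. The
  mode is a one-dimensional, log-concave problem; a damped Newton
  iteration is run vectorized across all participants simultaneously
  (tolerance 1e-9 on the gradient, steps capped at 10). Cell probabilities
  that underflow are replaced by their logistic tail limits (log-linear
  with slope one and zero curvature), which keeps the iteration finite for
  extreme parameters the optimizer may visit.
* **Initialization.** Cutpoints at the logit of the empirical cumulative
  proportions, slopes 0, log-SD 0. For the intercept-only model with the
  SD fixed at zero this initialization *is* the maximum-likelihood
  solution (the multinomial closed form), which the tests exploit as an
  exact oracle.
* **Optimizer.** BFGS with the analytic gradient of the Laplace
  objective, derived by implicit differentiation of the conditional
  modes (the mode shift envelope-cancels everywhere except in the
  curvature correction, which requires the third derivative of the
  conditional log-likelihood). The model matrix is centered internally —
  covariates with large means make cutpoints and slopes nearly collinear
  and stall quasi-Newton search — and the cutpoints are shifted back to
  the raw-covariate scale afterwards; the likelihood is invariant to
  this. Relative tolerance 1e-10, 500 iterations; non-convergence is
  reported in the `converged` field, never silently. Slopes exceeding 10
  in magnitude trigger a complete-separation warning.
* **Unobserved categories.** Rating categories never observed in a
  dataset have unidentified cutpoints; adjacent cutpoints are collapsed
  with a warning rather than failing.
* **Boundary tests.** Likelihood-ratio tests that put the intercept
  variance on its boundary use the naive chi-square reference, as the
  standard tooling for this model family does; the boundary issue is
  documented, not corrected. No multiple-testing adjustment is applied —
  tests are reported one at a time at the conventional 0.05 threshold.

### Accuracy of the Laplace approximation

The Laplace log-likelihood is validated against an independent 61-node
adaptive Gauss–Hermite quadrature oracle. The agreement is a property of
the approximation, not just the code, and it depends on the intercept SD:
on small groups (five or fewer observations) the gap is below 1e-3
log-units for SDs up to about 0.25, around 5e-2 at SD 1, and of order 0.2
(occasionally worse) at the perceived-control SD of 2.31. The test suite
therefore checks tight agreement in the small-variance regime, where the
second-order expansion is exact to the stated tolerance, and separately
pins the measured order of magnitude of the gap at the larger SDs so the
approximation's degradation is visible rather than hidden. Parameter
*recovery* at the published effect sizes is unaffected: with 200
participants by 4 conditions, the median estimates across 100 generation
seeds recover the generating slope within 0.1 and the intercept SD within
0.3.

`rank_models()` reproduces the model-comparison workflow: every candidate
fixed-effect set is fitted on identical observations, ranked by AIC
(`2k - 2 logLik`; ties keep input order), and tested against the
participant-only null by likelihood ratio.

## Agreement and association statistics

`icc3k()` is the two-way mixed, consistency, average-measures intraclass
correlation `(MS_items - MS_error) / MS_items`, used to quantify how
consistently participants rated each condition. Note that under pure noise
this ratio estimator is biased *below* zero when the item degrees of
freedom are small (Jensen's inequality applied to `1 - MSE/MSB`); the test
suite compares it against the exact null distribution `1 - 1/F` rather
than against zero. `spearman_rho()` delegates to the midrank-based rank
correlation and rejects constant vectors, for which the statistic is
undefined. `bartlett_sphericity()` implements the determinant-based
sphericity statistic used to decide whether a battery of new self-report
items warrants factor analysis.

## What the generator does and does not emulate

The synthetic stack emulates: scheduled recognition with agent-induced
dropouts, all three help mechanisms including both augmented-success
activation rules, the published session-measure definitions, and ordinal
ratings from the published effect sizes. It does not emulate: temporal
drift in posture or fatigue, learning across trials, crossed random
effects (fatigue, gender, condition order can enter as fixed covariates
only), wall-clock pacing, or the questionnaire item wording of the
follow-up study. Passing tests therefore demonstrate internal consistency
of the measurement and modeling pipeline under the stated generative
assumptions — not that real patients behave like the agents.

## Problem sizes used by the test suite

The conservation property runs 1,000 randomly configured sessions;
exhaustive-enumeration checks cover all spawn sequences for six-trial,
three-lane sessions; Monte-Carlo agent checks use 10,000 trials; the
parameter-recovery study uses 200 participants by 4 conditions over 100
generation seeds with covariates taken from simulated sessions. These
sizes were chosen to make the Monte-Carlo standard errors small relative
to the tested tolerances.

## A worked example

```{r example}
library(pamsim)

plan <- experiment_plan(n_participants = 19, agent = "ideal", seed_base = 1)
res <- run_experiment(plan)
res$summary

specs <- default_rating_specs()
ratings <- generate_ratings(res$measures, specs$perceived_control, seed = 1)
rank_models(ratings, list("fish_reel", "fish_lost", "condition"))
```
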