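---
title: "Adaptive thresholds, constrained psychometric fits and normative residual scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive thresholds, constrained psychometric fits and normative residual scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psynorm)
```

`psynorm` implements the statistical pipeline of case-control behavioral
recognition studies — the prototypical application being congenital
prosopagnosia (CP), a lifelong face-identification deficit studied against
age-matched controls. The pipeline has four methodological stages, each
exposed as ordinary R functions, plus a synthetic cohort generator that
stands in for participant data so that every stage can be validated end to
end.

## The adaptive staircase

Presentation-time thresholds are estimated online with accelerated
stochastic approximation. With answers $z_n \in \{0,1\}$ (1 = correct), a
target fraction $\varphi$ and an initial step constant $c$, the
presentation time evolves as

$$x_{n+1} = x_n - \frac{c}{2 + m_n}\,(z_n - \varphi),$$

where $m_n$ counts the shifts correct$\leftrightarrow$incorrect over the
answer history (counting starts with the second answer). Errors lengthen
presentation, correct answers shorten it, and every reversal shrinks the
step. At $\varphi = 0.8$ the procedure settles where the observer is right
80% of the time, and the threshold estimate PT80 is the arithmetic mean of
the last 16 presented times.

CRT monitors present in whole frames, so every *presented* duration is
quantized to `max(1, round(x * frame_rate / 1000))` frames (5 ms steps at
200 Hz, about 5.88 ms at 170 Hz). The recursion itself, however, runs on a
continuous internal state. This is a deliberate design choice: once
$c/(2+m)\,(1-\varphi)$ falls below half a frame, a recursion carried on the
quantized value can no longer move downward (sub-frame decrements round
back to the same frame count) while the larger error-driven increments
still move upward — a ratchet that drives the procedure away from the
threshold instead of onto it. With the continuous state, 500 simulated
64-trial runs on an ideal observer average 80–81% correct over their final
16 trials; with a quantized state the same runs drift above 90%.

Defaults are `x_init = 200` ms and `c = 100` ms; both are explicit
arguments everywhere so that runs are reproducible. An upper clamp at
2000 ms (counted and reported, never silent) guards against divergence for
near-chance observers.

## The constrained psychometric function

Accuracy as a function of presentation time $x$ is modeled as

$$p(x) = \gamma + (1 - \gamma - \lambda)\,F(x;\alpha,\beta),$$

with the guess rate $\gamma$ fixed by the design (0.5 for 2AFC, 0.25 for
4AFC), the lapse rate bounded $0 \le \lambda \le \lambda_{\max}$
(default 0.05), and $F$ the logistic CDF with location $\alpha > 0$ and
slope $\beta > 0$. The inner term defaults to the linear-ms scale,
$F = \mathrm{plogis}(\beta(x - \alpha))$: on this scale $\alpha$ is itself
a presentation time, which is what gives the positivity constraint its
meaning. A log-ms predictor scale is available by argument.

Fitting maximizes the Bernoulli likelihood with analytic gradients from
eight deterministic starting points plus the best cell of a coarse
$50\times50\times5$ grid, under box constraints — seedless, reproducible,
and verified in the tests to dominate a dense grid search. Convergence is
declared only when the KKT-projected gradient norm is small, so a fit
pinned at the lapse bound is not spuriously flagged. Degenerate data (all
answers identical) return a flagged boundary fit rather than an error.
Location uncertainty is summarized by a 95% profile-likelihood interval
(a bootstrap is deliberately not used).

Criterion times are obtained by closed-form inversion,
$x^\ast = \alpha + \mathrm{qlogis}\!\big((p^\ast-\gamma)/(1-\gamma-\lambda)\big)/\beta$;
the 90% criterion (PT90) is used to set the fixed presentation time of the
rotation experiments — for each CP participant and both of their matched
controls.

When we validate the closed loop (fit, invert at 90%, simulate fresh
trials at $x^\ast$), the fitting data are eight pooled 64-trial staircase
runs (512 trials): that is the shape a session of the staircase experiment
actually produces, with repeated descents from `x_init` that pin down the
slope. A single 500-trial run instead freezes at one level once the steps
shrink, leaving the slope ill-determined; in our simulations the pooled
design is unbiased (mean 90.3% at the 90% criterion) where the single long
run is biased low (88.3%) with wider spread.

## Preprocessing rules

Reaction-time analyses use feedback-training trials, pooled across the
staircase and rotation experiments of the same stimulus class. Filters are
applied in a fixed order with per-rule audit counts (malformed rows, first
training block, incorrect answers, RT cutpoints); the audit reconciles
exactly and filtering is idempotent. Cutpoints dismiss values strictly
below 500 ms or strictly above 2000 ms (values exactly at a bound are
kept — the dismissal rule speaks of values *above* and *below* the
cutpoints); experiment-specific presets use 500–8000 ms and 500–4000 ms
for the two delayed-matching experiments. Reaction times are modeled as
$-1/\mathrm{RT}$ in seconds (larger = slower, so a positive group
coefficient means slower cases); thresholds are modeled as
$\log \mathrm{PT80}$, and trial-level presentation times as log-ms,
mean-centered over the dataset.

## Mixed-model ladders and likelihood-ratio tests

Each experiment is analyzed with a nested ladder: a *nullmodel* holding
age and the experimental variables with participant random effects, then a
*group main effect*, then *group-by-variable interactions*. Concretely:

* staircase experiments, RT: $-1/\mathrm{RT} \sim$ age + block, random
  intercept and block slope (unstructured 2×2); then + group; then
  + group:block;
* staircase experiments, thresholds: $\log \mathrm{PT80} \sim$ age (one
  observation per participant, fixed effects only); then + group;
* rotation experiments, correctness (binomial logit): age + rotation
  (nominal by absolute angle, so ±30° is one level) + centered log PT,
  random intercept; then + group; then + group:PT (the *PT interaction
  model*); then additionally + group:rotation (the *full interaction
  model*);
* delayed-matching experiments: age + log PT with random intercept, the
  same ladder for correctness and for $-1/\mathrm{RT}$.

All fits are maximum likelihood (never REML — REML likelihoods of models
with different fixed effects are not comparable); Gaussian models go
through `lme4::lmer`, binomial ones through `lme4::glmer` with 9-node
adaptive Gauss–Hermite quadrature for random-intercept structures. The
test suite verifies the binomial marginal likelihood against an
independent 51-node quadrature oracle to $10^{-4}$ nats, and the Gaussian
path against the closed-form least-squares limit when the random variance
vanishes.

Nested fits on the same data (enforced by an order-independent data
fingerprint) are compared by $\chi^2$ likelihood-ratio tests with degrees
of freedom equal to the difference in parameter counts. This reference
distribution is mildly anti-conservative for fixed effects in mixed
models; the package therefore reports Wald intervals from the ML fit for
interaction effects rather than re-fitting a Bayesian model, and flags
them as approximations.

## Cross-validated residual scores

Abnormality scores ask how far a participant sits from a *hypothetical
average control with the same covariates*. The nullmodel is fitted to
control observations only; its fixed effects (random effects set to zero)
predict each CP observation, and residuals are averaged into one score per
participant. Each control is scored leave-one-out: the reference is refit
without that control (warm-started from the all-controls fit, convergence
re-verified), so nobody is judged by a model that saw their own data.
Gaussian residuals live on the modeled (transformed) response scale. For
binomial responses the default is the link scale — the participant's
continuity-adjusted empirical logit minus the mean predicted logit — with
a response-scale option; a conditional (random-effects-included) variant
exists for sensitivity analysis. Groups are compared on the scores with
rank tests: Wilcoxon rank-sum (exact null distribution when the combined
sample is ≤ 30 without ties, otherwise a normal approximation with
continuity and tie corrections) and the signed-rank analogue for paired
designs (exact for n ≤ 25). The exact branches are verified against full
enumeration in the tests.

## The synthetic cohort generator

The generator emulates the population and designs the analyses assume: by
default 16 CP observers with 2 age-matched controls each, ages from a
two-component Gaussian mixture (younger cluster 23 ± 2 years, older
54 ± 9), a 170 or 200 Hz monitor per matched triplet, and control
thresholds lognormal around 21 ms with a mild multiplicative age slope.
CP thresholds carry a configurable multiplier (default 1.6, in the region
of reported CP/control threshold ratios; the power analyses in the tests
use 2.0 as their stated condition). Accuracy follows each observer's
psychometric function with rotation entering as an additive log-odds
penalty per 30° step, identical across groups unless an interaction flag
is enabled. Reaction times are generated on the $-1/\mathrm{RT}$ scale as
a linear predictor (intercept, age, block, group shift, participant random
intercept and block slope) plus Gaussian noise, rejection-sampled into
(0, 20 s) with a capped loop; the default block coefficient is negative
(practice speeds responding). Defaults were chosen once to give control
reaction times around 600–700 ms and are not tuned per analysis.

Experiment templates reproduce the design-level counts: staircase test
blocks of 8 with every target exactly once; two 56-trial rotation blocks
for faces (7 conditions × 4 targets + 4 distractors) and four 24-trial
blocks for shoes; 192 4AFC trials as 48 stimuli × 4 presentation times
with a cyclic Latin-square counterbalance (each stimulus serves as target
exactly once per time — the original scheme is not specified, a Latin
square is the canonical choice); and 12 cycles of 8 training + 32 test
trials with durations 50/150/450/750 ms balanced 8:8 per duration within
each cycle. Matched controls receive their CP's stimulus orderings
exactly; all orderings and answers descend from a single root seed through
labeled substreams, so regeneration is byte-identical and enlarging a
cohort never perturbs existing observers. The unlimited presentations of
feedback training are encoded as `Inf`, never as a large number, and are
exempt from frame quantization.

What the generator does *not* emulate: real stimulus images (stimuli are
abstract tokens), gaze or fixation behavior, sequential dependencies
between trials (answers are conditionally independent given the
psychometric function), non-Gaussian RT shapes beyond what the inverse
transform induces, and training-phase learning dynamics (training accuracy
is stationary at 1 − lapse). Passing tests therefore demonstrate that the
*statistical machinery* is correct and calibrated under the assumed
generative structure — not that the assumptions hold for any particular
real dataset.

## Numerical choices and degenerate inputs

* Frame rounding uses R's `round` (half-to-even); quantization error is at
  most half a frame except at the one-frame floor.
* The staircase clamp (2000 ms), the RT rejection cap (1000 redraws) and
  the psychometric box bounds are explicit constants; hitting them is
  either counted, flagged or raised, never silent.
* `lme4` fits use the `bobyqa` optimizer with a raised evaluation cap;
  singular variance components are reported via a `boundary` flag, and
  `lr_test()` refuses non-converged inputs outright.
* Wilcoxon ties take midranks everywhere; exact branches are disabled in
  the presence of ties.
* Unattainable inversion criteria ($p^\ast \notin (\gamma, 1-\lambda)$)
  raise an error naming the feasible interval.

## Problem sizes used in the validation suite

The test suite and the acceptance script regenerate everything they check.
Sizes were fixed once as the package's own choices: 500 replicates of
64-trial staircases for the threshold calibration; 8 × 64 pooled trials
per closed-loop psychometric fit; 200 replicates of 500-trial datasets for
parameter recovery; 400 replicates at the study's 16-vs-32 cohort size
(32 RT observations per participant) for type-I calibration of the group
likelihood-ratio test; 400 replicates for rank-sum calibration on
leave-one-out residual scores; and 200 replicates at threshold multiplier
2.0 for power. The full simulated study (`run_full_study()`) defaults to
the study-scale cohort but is routinely exercised at reduced size.

## Known limitations

* The chi-square reference for LR tests on fixed effects in mixed models
  is anti-conservative at this cohort size; measured type-I error sits
  near the top of its tolerance band. Interpretation should lean on the
  residual-score rank tests, which are calibrated by construction.
* The lapse rate is weakly identified from staircase-concentrated data;
  it is bounded, not estimated freely, and the bound is a configuration
  choice surfaced in every interface.
* Residual scores for binomial responses depend on the chosen scale
  (link vs response); the default is stated, not canonical.
* The generator's null is exchangeable by construction; real cohorts may
  differ between groups in ways (RT variance, lapse rates) that the
  scoring procedure would register as abnormality.
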