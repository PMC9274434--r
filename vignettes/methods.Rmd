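---
title: "Models and methods behind dotlattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dotlattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

When an ambiguous dot lattice is viewed repeatedly, what an observer
perceives on one trial depends on the recent past in two opposing ways.
*Hysteresis* attracts the current percept toward the previous percept;
*adaptation* repels it from the organization that the previous stimulus
supported most. In the two-lattice paradigm implemented here, a
rectangular first lattice (L1) whose aspect ratio AR = |a|/|b| varies
over 1.3^-1 ... 1.3 is followed by an ambiguous hexagonal second lattice
(L2). The observer reports the perceived organization of both via 4-AFC
responses. Because the effects are defined on the logit scale of the
probability of reporting the 0-degree organization, both can be read off
one multilevel logistic regression, and individual differences in the two
effects become the random slopes of that regression.

`dotlattice` provides the full analysis pipeline for this design:
a synthetic-observer generator, the hierarchical Bayesian model family,
Bayes-factor machinery (bridge sampling, encompassing-prior counting,
one-sided Savage-Dickey ratios), axial circular statistics for the
absolute-orientation-bias task, and an orchestration layer.

## Preprocessing

Only response alternatives that are equally likely at AR = 1 enter the
model: trials with a diagonal L1 report or a 90-degree L2 report are
dropped (`to_binary_trials()`); this filtering is part of the contract,
not an error. The retained reports are coded r1 = 1 and y2 = 1 for the
0-degree organization, and AR is centered (AR - 1) so that zero is the
maximally ambiguous lattice. Participants are excluded when a required
session is incomplete or when their diagonal-response proportion in the
main task strictly exceeds 40% in a required session — "more than 40%"
is read as a strict inequality, and the threshold is a parameter of
`apply_participant_exclusions()`.

For descriptive displays, `empirical_logits()` computes per-cell observed
log-odds. Cells at the boundary (0 or n successes) would give infinite
logits; we apply a Haldane–Anscombe-style continuity constant c = 0.5 to
both counts *only at boundary cells*, leaving interior cells untouched.
This is an implementation choice: boundary handling in the descriptive
figures of this literature is typically not specified.

## The hierarchical model

For participant i and trial l, the second-lattice percept is

y2 ~ Bernoulli(p),  logit(p) = (b0 + b0i) + (bAR + bARi) * AR_c +
(bR1 + bR1i) * r1,

with fixed effects (b0, bAR, bR1) and participant deviations drawn from a
trivariate normal with SDs (s0, sAR, sR1) and a full correlation matrix.
bR1 is the hysteresis effect, bAR the adaptation effect, and in the
companion first-lattice model (outcome r1, predictor AR_c) the slope is
the proximity effect. An optional AR-by-r1 interaction extends the model.

Implementation notes, in the order they matter:

* **Binomial collapsing.** Trials are collapsed to binomial counts per
  (participant, session, AR cell, r1) — at most 14 cells per participant
  per session — which leaves every likelihood ratio unchanged and makes
  desk-scale MCMC and bridge sampling fast. The log-likelihood is kept in
  the Bernoulli-trials convention (no binomial coefficient) so that model
  variants that collapse cells differently (e.g. a model without the AR
  term) remain comparable in marginal likelihood.
* **Sampling.** Models are fitted with JAGS (rjags), using a non-centered
  parameterization: deviations are diag(sigma) L z with standard-normal z
  and L the Cholesky factor of the correlation matrix, built from
  vine coordinates u with independent Uniform(-1, 1) priors. Chains are
  seeded explicitly, so every fit is exactly reproducible.
* **Priors.** Fixed effects Normal(0, 2.5) on the logit scale;
  random-effect SDs half-Student-t(3, 2.5); correlation coordinates
  uniform. These are zero-centered and weakly informative at the scale of
  logit effects of a few units; all values are exposed in
  `percept_priors()` and recorded on the fit. Because priors enter Bayes
  factors directly, prior-scale sensitivity should be checked when
  absolute BF magnitudes matter; the package's tests rely on BF
  directions and analytic oracles, not on absolute magnitudes.
* **Sign constraints.** The positive-effects (or negative-effects) model
  constrains only the *population mean*, using a truncated-normal prior
  (`T(0,)` in JAGS). Truncation keeps the constrained prior exactly equal
  to the unconstrained prior restricted to the half-line, which is
  coherent with the encompassing approach used to test whether *every
  individual* shows the effect; JAGS samples the truncated node exactly,
  without rejection.
* **Sampler scale.** The replication-scale configuration is 4 chains of
  20,000 iterations; the package default (4 x 1,500 after 1,000 warmup)
  and the problem sizes used in the tests (cohorts of 8-40 observers,
  210-630 trials each) are desk-scale choices that keep the full suite
  in minutes while leaving Monte-Carlo error far smaller than the effects
  tested. Fits are flagged (not failed) when split-R-hat exceeds 1.01 or
  a top-level effective sample size falls below 400.

### Session structure

Cross-session stability is modeled jointly over the two sessions with
per-session fixed effects and SDs. Each term's individual deviations are
bivariate across sessions with correlation rho, and the model family sets
rho for the tested effect to 0 (uncorrelated), a free parameter
(correlated), or 1 by construction via a shared standardized deviation
(fully correlated); the other terms keep a free rho. In the joint models
the deviations of different terms are independent — the cross-term
correlation matrix is estimated only in the single-session models. This
keeps the joint family identified at desk scale; the within-session
hysteresis–adaptation correlation is reported from the single-session
full model.

## Bayes factors

* **Bridge sampling** (`bridge_log_ml()`): iterative optimal bridge with
  a moment-matched multivariate-normal proposal on unconstrained
  parameters (log SDs, atanh correlations). Half the posterior sample
  fits the proposal, the other half enters the recursion (tolerance
  1e-10, at most 1,000 iterations). The estimator is validated against
  closed-form evidence on normal-normal and beta-binomial problems to
  within 0.05 log units. A fit's marginal likelihood is estimated with a
  deterministic proposal seed, so log BF(a,b) = -log BF(b,a) exactly and
  transitivity holds exactly.
* **Encompassing approach** (`encompassing_bf()`): the constrained-model
  BF is the ratio of the posterior to the prior probability, under the
  unconstrained model, that every participant's total effect satisfies
  the sign constraint, both estimated by counting draws. Prior draws come
  from forward simulation of the model prior. Zero posterior hits yield a
  finite one-sided bound (1/N over the prior proportion), flagged as a
  bound rather than reported as infinity.
* **Savage-Dickey one-sided tests** (`savage_dickey_onesided()`): for a
  correlation with a symmetric prior, the BF is the posterior odds of the
  tested sign. Correlation posteriors come from a bivariate-normal model
  with a Uniform(-1, 1) prior on r (`bayes_cor()`), fitted to
  posterior-mean individual effects. This two-stage construction is one
  of two defensible readings of "correlation based on the full model";
  the hierarchical model's internal correlation posterior is reported
  alongside so both are available. A quadratic-versus-linear variant of
  the bias-effect relation is provided by bridge sampling two Bayesian
  regressions with standardized predictors and matched priors.
* **Sequential design** (`sequential_rule()`): monitoring starts at 30
  participants and proceeds in steps of 5; collection stops when every
  monitored BF leaves the (1/6, 6) band, and unconditionally at 75.

## The synthetic observer

`simulate_study()` generates the full replica design: per session, nine
main-task blocks of 70 trials with each of the seven aspect ratios
exactly 10 times per block in shuffled order; a 90-trial control task in
session 1 whose first lattice is random (no orientation support); and a
four-block orientation task presenting each absolute orientation 1-60
degrees once per block. Responses follow the generative counterpart of
the model: L1 reports from logit(p) = intercept_l1 + proximity * AR_c,
L2 reports from the hysteresis/adaptation model, and orientation-task
reports from an axial von-Mises-type weight
exp(concentration * cos 2(candidate - preferred direction)) over the
three dominant candidates.

Default population values are chosen at the centre of the effects
reported for this paradigm: hysteresis 2.3, adaptation 2.0 (logit units,
between-person SD 1.0 each, correlation 0.7), a strongly negative
proximity slope (-8, SD 2), cross-session correlations of 0.8-0.95, and
a control-task carry-over scale of 0.4 (a residual decisional component
of hysteresis when the first lattice is random — the generator's account
of the reduced but nonzero control-task effect). Non-dominant responses
come from a single lapse parameter: with probability 0.15 a report is
drawn uniformly from the non-dominant options (the two diagonals for L1;
60/120/90 degrees for L2). That value makes the expected share of
main-task trials dropped in preprocessing about 19%, matching the
design's preprocessing bookkeeping. Lapses are deliberately *not* part of
the estimation model; they attenuate logit effects, which is a property
of any logistic analysis of lapse-contaminated data. Parameter-recovery
checks therefore run on lapse-free cohorts — what they certify is the
estimation machinery, not robustness to lapsing. Similarly, the
generator's independence and stationarity assumptions (no drift, no
block effects, no response-position memory) mean that green tests
certify the pipeline on data satisfying the model's assumptions, not the
model's adequacy for any particular real dataset.

## Numerical choices and degenerate inputs

* Orientation direction uses the quadrant-aware atan2 form of
  (1/2) arctan(sum sin 2theta / sum cos 2theta), mapped into [0, 180).
* Participants whose orientation-task responses are all 90 degrees have
  no defined bias; they are flagged with NA magnitude, not dropped
  silently.
* The bridge proposal covariance is ridge-regularized by 1e-6 of its mean
  diagonal, which only widens the proposal slightly.
* HDCIs are shortest intervals from sorted draws; ties in interval width
  resolve to the first (lowest) window.
* Boundary Savage-Dickey counts (all draws on one side) are reported as
  the bound implied by one contrary draw, flagged as bounds.
* The cross-session generator uses a shared-factor construction
  (deviation = sqrt(rho) shared + sqrt(1-rho) unique), which is positive
  semidefinite by construction but restricts session correlations to
  [0, 1] — negative test-retest correlations are outside the generator's
  scope, and it errors on them.

## Known limitations

* Absolute Bayes-factor magnitudes at replication scale (for example 
  astronomically large values obtained at full scale on real data) are
  Monte-Carlo estimates far
  outside verifiable precision; the package targets BF *directions* and
  estimator correctness instead, and treats printed magnitudes of that
  kind as non-reproducible by design.
* The lapse process is generative only; fitting a lapse-mixture logistic
  model is out of scope.
* Joint models omit cross-term correlations (see above).
* `predict()` is implemented for single-session fits.
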