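# dotlattice

Individual differences in serial dependence for multistable dot-lattice
perception: who is pulled toward what they just saw, who is pushed away
from what the stimulus just supported, and are these stable traits?

`dotlattice` implements the complete analysis pipeline for the
two-lattice paradigm. A rectangular dot lattice L1 with aspect ratio
AR = |a|/|b| (1.3⁻¹ … 1.3) is followed by an ambiguous hexagonal lattice
L2; observers report both percepts via 4-AFC responses. Two context
effects live in one Bayesian multilevel logistic regression of the
second percept,

```
y2 ~ Bernoulli(p)
logit(p) = (β₀ + β₀ᵢ) + (β_AR + β_ARᵢ)·(AR − 1) + (β_R1 + β_R1ᵢ)·r1
```

where `r1` indicates that L1 was perceived in the 0° organization.
β_R1 is the **hysteresis** (attraction) effect, β_AR the **adaptation**
(repulsion) effect, and the per-participant random slopes β_ARᵢ, β_R1ᵢ
carry the individual differences. A companion model of the first percept
(`r1 ~ AR`) measures the **proximity** effect, and an axial circular
analysis summarizes each observer's absolute orientation bias as a
vector magnitude L (0–100%) and direction θ̄ over doubled angles.

The package provides:

* a **synthetic observer** (`simulate_study()`) generating the full
  replica design — per session 9 × 70 main-task trials (7 aspect ratios
  balanced within block), a 90-trial control task with a random first
  lattice, and a 240-trial orientation-bias task — with ground-truth
  effects for recovery testing;
* **hierarchical model fitting** via JAGS (`fit_percept_model()`,
  returning a `percept_fit` with `print`/`summary`/`coef`/`predict`/
  `plot`/`simulate`/`residuals` methods), including common-effects,
  sign-constrained and joint two-session variants;
* **Bayes factors**: bridge-sampling marginal likelihoods
  (`bridge_log_ml()`, `bf_bridge()`), encompassing-prior tests of
  "does everyone show the effect" (`encompassing_bf()`), one-sided
  Savage–Dickey correlation tests (`savage_dickey_onesided()`,
  `bayes_cor()`), and the cross-session correlation model family
  (`compare_session_models()`);
* **preprocessing and exclusions** (`to_binary_trials()`,
  `apply_participant_exclusions()`, `empirical_logits()`), **circular
  statistics** (`orientation_vector()`, `bias_per_participant()`,
  `circular_circular_correlation()`), the **sequential stopping rule**
  (`sequential_rule()`), and an end-to-end pipeline (`run_replica()`).

## Worked example

Simulate a small cohort with known effects, fit the full model, and test
for hysteresis:

```r
library(dotlattice)

design <- design_spec(n_participants = 10, n_blocks = 3)
study  <- simulate_study(design, population_params(lapse_rate = 0),
                         sessions = 1, tasks = "main", seed = 21)
trials <- to_binary_trials(study$trials)

fit <- fit_percept_model(trials, "full",
                         sampler = sampler_config(2, 800, 600, seed = 3))
fit
#> Hierarchical percept model fit (full)
#>   outcome: y2 | sessions: single
#>   fixed terms:  intercept, ar, r1
#>   random terms: intercept, ar, r1
#>   participants: 10 | cells: 138 | trials: 2100
#>   draws: 2 chains x 800 | max split-Rhat 1.069 | min ESS 25 [flagged unreliable]
#>  intercept         ar         r1
#> -0.9750177  2.0850141  2.9409846

no_hyst <- fit_percept_model(trials, "no-hyst",
                             sampler = sampler_config(2, 800, 600, seed = 3))
bf_bridge(fit, no_hyst)
#> Bayes factor (bridge): log BF = 247.231 (BF = 2.35e+107), favoring full
#>   approximate MC error (log scale): 0.426
```

The generating population here has mean hysteresis 2.3 and adaptation
2.0 logits: the fixed-effect posterior means land close to the truth
(`ar` 2.09, `r1` 2.94 — the cohort of ten's realized
mean hysteresis is itself a draw around 2.3), and the evidence for including the
previous-percept term is overwhelming. (The short demonstration chains
are flagged by the reliability diagnostics; the package default is
4 × 1,500 draws, and 4 × 20,000 is the full replication scale.)
Per-participant effects and their
95% highest-density intervals come from
`individual_effect_summaries(fit, "r1")`, and
`encompassing_bf()` tests whether *every* participant's effect is
positive.

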