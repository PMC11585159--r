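---
title: "Estimand strategies for longitudinal PROs in single-arm trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimand strategies for longitudinal PROs in single-arm trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proestimand)
```

## The problem

Patient-reported outcomes (PROs) such as a 0–100 global quality-of-life
(QoL) score are measured repeatedly in oncology trials, but the quantity "mean
QoL at cycle t" is not well defined until one says what happens to patients
who die, progress, or stop treatment before cycle t. PROs after death are
neither observable nor defined; PRO collection typically ends at treatment
discontinuation (TD) apart from one final questionnaire; and in a single-arm
trial there is no comparator to absorb these problems. The estimand
framework resolves this by making five choices explicit: the treatment, the
population, the variable, the population-level summary, and one handling
strategy per intercurrent event. This package implements the full pipeline
for a single-arm setting — simulation with known ground truth, description
of missingness, event-conditioned imputation, and estimation under every
supported strategy combination — with the per-cycle mean as the population
summary throughout.

## Strategies and their estimators

For **death** three strategies are supported, each hard-wired to the
estimator that actually targets it:

* **While alive** — the target is the mean among patients alive (and under
  follow-up) at each cycle. Two routes: a GEE with independence working
  correlation and cycle as a saturated categorical covariate, whose point
  estimates are exactly the per-cycle descriptive means; or a linear mixed
  model (LMM) whose individual predictions are averaged over only the
  patients alive at each cycle. A while-alive series is a conditional
  quantity and must be read jointly with the Kaplan–Meier survival curve,
  which `estimate()` attaches automatically.
* **Composite** — death is absorbed into the outcome at a fixed value
  (default 0, as in health-utility scores where 0 is death). The value is a
  reporting parameter, not a scientific constant, and is printed in every
  label. Estimated by the same independence GEE after appending the
  composite rows.
* **Hypothetical** — the mean in a counterfactual trial without deaths.
  Marginal means from an LMM fitted to the pre-death data deliver exactly
  this: the model's random-effects structure extrapolates each trajectory
  past death under an MAR-given-the-model assumption. *How* it
  extrapolates is a modelling choice, which is why both a random-intercept
  and a random-intercept-plus-slope variant are provided and compared by
  likelihood ratio.

For **treatment discontinuation** and **disease progression**: *treatment
policy* (use all data regardless of the event — the intention-to-treat
analog, requiring data, usually imputed, after the event), *while on
treatment* / *while progression-free* (drop data strictly after the event
cycle; the final questionnaire at the TD cycle counts as on-treatment), and
*hypothetical* (fit the LMM to pre-event data and predict beyond it). A
while-on-treatment or while-progression-free strategy forces a while-alive
handling of death, since neither state survives it; a composite value for
TD or PD is not offered because no single QoL value meaningfully represents
"discontinued". `estimand_spec()` rejects any other combination and names
the violated rule.

### An exact identity worth knowing

On a *complete* dataset (one row per alive patient-cycle), the
survivor-averaged LMM equals the per-cycle descriptive mean exactly, not
approximately: with saturated categorical time and a diagonal residual
covariance, Henderson's mixed-model equations force the per-cycle residual
sum over contributing patients to zero, and the averaging set coincides
with the contributing set. The two while-alive routes therefore differ only
on incomplete data or non-saturated time codings. The test suite asserts
the identity to 1e-6; "the two routes agree" is structural, not an
empirical coincidence.

## The synthetic trial generator

The generator (`simulate_trial()`) is discrete-time: everything happens on
the 3-week cycle grid, matching the cycle-indexed estimators (no
continuous-time machinery is needed for any supported analysis). Defaults
encode the study conditions of a large single-arm lung-cancer cohort:

* 876 patients; latent QoL rises linearly from 54 at cycle 1 to 67 at
  cycle 4 (SD at baseline 25 points, split into a patient-level frailty,
  SD ≈ 21.9, and residual noise, SD 12), then stays flat;
* a per-cycle death hazard with a logistic link to the current smooth
  latent QoL, `plogis(-3.5 - 0.03 (QoL - 50))` — roughly 1.7%/cycle at the
  plateau — chosen so that survival is ≈ 68% after one year and ≈ 46% at
  cycle 40 and so that baseline QoL predicts survival, without committing
  to a stronger mechanism than those facts support;
* a linear QoL drop of 4 points/cycle over the final 5 cycles before
  death;
* disease progression with a constant hazard of 0.05/cycle, followed by
  treatment discontinuation after a lag of `1 + Geometric(0.3)` cycles
  (median ≈ 2–3 cycles, with a tail of patients continuing much longer); a
  configurable 5% discontinue without progression; latent QoL steps down 5
  points after TD;
* measurement every cycle through cycle 10 (30 weeks), alternate cycles
  thereafter; collection ends at TD except the final TD-cycle
  questionnaire; 7% baseline item missingness plus 15% extra within 5
  cycles of death or after PD;
* purely administrative censoring, a cycle drawn uniformly on 41–60,
  independent of everything — so censoring is non-informative by
  construction and almost never occurs inside the analyzed 40 cycles.

The hazard acts on the *smooth* latent level (population curve + frailty),
not on the noisy or drop-affected value: letting the pre-death drop feed
the hazard that defines death would be circular. Two non-obvious
consequences of the drop are documented because they shaped the tests:
patients who die within the first window already carry drop at cycle 1, so
the empirical cycle-1 mean sits about a point below the nominal 54 (the
clipping to [0, 100] contributes another ≈ 0.2); and the drop by itself
couples baseline QoL to survival even when the hazard ignores QoL.
Calibration checks therefore disable the drop, and "no coupling" checks
disable the drop, the frailty, and the QoL–hazard link together.

What the generator does *not* emulate: informative censoring, QoL measured
after death (impossible), continuous-time event processes, multi-arm
structure, item-level questionnaire data, and any dependence of PD on QoL.
Passing recovery tests on this generator shows the estimators are faithful
to their targets under the stated mechanism — not that any real trial
satisfies MAR or non-informative censoring.

`compute_ground_truth()` replays the structural draws at large n (default
20,000, with its own seed) and returns the true while-alive mean, the true
no-death counterfactual mean (same draws, death and its drop switched off,
TD decrement retained), and true survival, each with Monte Carlo standard
errors. This is the oracle for the parameter-recovery tests.

## Imputation

`impute_single()` creates one completed dataset per run: a single pooled
linear regression of observed QoL on cycle (categorical), the last
available value and its distance in cycles, PD-by-now, after-TD,
death-observed, within-5-cycles-of-death, and cycles-to-death, fitted once
to all observed rows, then applied in cycle order with forward chaining (an
imputed value becomes the "last available" for later cycles — needed to
define that predictor across long gaps). Values are imputed before and
after PD/TD but never at or after death, and are clipped to [0, 100].
Residual draws (seeded) are the default so per-cycle variances are not
deflated; conditional-mean imputation is a switch. Design notes:

* For censored patients the death-proximity predictors are zero: no
  anticipation of unobserved deaths.
* Cycles never observed for anyone (the unscheduled odd cycles after 10)
  borrow the nearest observed cycle's categorical effect.
* Predictors aliased with the cycle effects are dropped with a warning
  (complete panels make the gap predictor collinear with the cycle-1
  dummy); a design with no fittable model — e.g. all values at one cycle —
  is an error.
* Patients with no observed values are imputed from the population model
  and flagged; single imputation understates uncertainty by construction,
  which is why the package reports it as an illustration device, not an
  inferential method. Multiple imputation is out of scope.

Because missingness concentrates near death and after PD and the model
conditions on those events, the completed dataset's late-cycle means sit
below the available-data means — the direction one should expect whenever
sicker patients stop reporting.

## Numerical choices

* Cycles are 1-based closed integers; cycle 40 ends every analysis.
* Within-cycle duplicate reports are averaged before anything else;
  baseline is the cycle-1 value after that averaging.
* Discrete-cycle Kaplan–Meier (via `survival::survfit`): events precede
  censoring within a cycle; composite events (PD-or-death, TD-or-death)
  use the earlier component cycle; CIs on the log(−log) scale by default
  (a plain Greenwood option exists); the median is the first cycle with
  S ≤ 0.5, flagged explicitly when never reached.
* GEE point estimates come from OLS on saturated cycle dummies — which *is*
  the independence-GEE solution — with cluster-robust (sandwich) SEs;
  cycles with one observation report no SE, empty cycles warn and are
  skipped.
* LMMs are REML fits (`lme4`); the random slope uses a centered scaled
  cycle, (t − 20)/20, for conditioning stability while fixed effects stay
  categorical. Model comparison refits by ML; the LRT reference is a plain
  chi-square with 2 df, conservative at the variance boundary.
* Survivor-averaged SEs are delta-method SEs on the fixed effects,
  treating empirical-Bayes predictions as fixed — an acknowledged
  approximation; no SE recipe for this estimator is standard.
* "Alive at cycle t" for averaging sets means alive *and under follow-up*,
  matching the GEE risk set under non-informative censoring.
* All CIs are normal-approximation 95% intervals.
* Random-effect structures richer than intercept+slope (e.g. spline random
  effects) are deliberately not offered; they are known to be unstable at
  this design's data density.

## Problem sizes in the tests

The recovery study uses 200 simulated trials of 500 patients against a
20,000-patient ground-truth oracle; LMM variance-component recovery uses
100 balanced replicates of 500 patients; the ordering and agreement checks
use single trials of 800–1,000 patients; imputation safety runs 100 trials
of 30 patients. These sizes give Monte Carlo error well below the assertion
tolerances while keeping the default suite runnable on a laptop in a few
minutes.

## Limitations

Single imputation, single-arm scope, no weighted GEE or joint models for
informative censoring, no time-to-deterioration endpoints, and no
item-level scoring (inputs are pre-scored 0–100 values). The hypothetical
estimands inherit every assumption of the LMM that realizes them; when a
large fraction of the cohort dies early, the no-death counterfactual may
answer a question no stakeholder is asking — the reporting layer prints the
full estimand with every series so that this is at least visible.
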