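---
title: "Modelling glucose- and insulin-dependent counter-regulatory hormone secretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling glucose- and insulin-dependent counter-regulatory hormone secretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(counterreg)
```

## The system and the model

During a hyperinsulinemic hypoglycemic clamp, insulin is infused while a
variable glucose infusion holds plasma glucose at prescribed targets —
normoglycemia (5.0 mmol/L) followed by hypoglycemia (2.7 mmol/L) and a
recovery phase; a hyperglycemic clamp instead steps glucose to +3, +6 and
+9 mmol/L above the fasting level. Falling glucose triggers the
counter-regulatory hormones: glucagon from pancreatic alpha cells and, via
the hypothalamic-pituitary-adrenal axis, ACTH and cortisol. `counterreg`
implements a population (nonlinear mixed-effects style) pharmacodynamic
model of these three hormones as driven by plasma glucose and insulin,
together with simulation of the clamp designs, synthetic data generation,
maximum-likelihood estimation, model comparison, bootstrap uncertainty,
stepwise covariate modelling, visual predictive checks, and the derived
suppression thresholds.

Each hormone follows a turnover (indirect-response) model: zero-order
secretion `k_secr` and first-order removal `k_out`,

```
dC/dt = k_secr * m(t) - k_out * C,
```

where `m(t)` is a secretion modifier. The final configuration is:

* **Glucagon** — secretion inhibited additively by glucose and insulin:
  `m = 1 - [frac * H(G; IC50_G, gamma_G) + (1 - frac) * I / (I + IC50_I)]`,
  with `H` the sigmoidal Hill function and `frac` the fractional effect
  attributed to glucose in the absence of insulin. The insulin term
  carries no Hill factor (removing it does not change the achievable fit;
  a variant with one is available through `model_variant()`).
* **ACTH** — secretion inhibited by *delayed* glucose:
  `m = 1 - Imax_A * H(Ge; IC50_A, gamma_A)`, where `Ge` follows the
  effect-compartment equation `dGe/dt = (ln 2 / t_half) * (G - Ge)`. The
  supremum of the inhibition is `Imax_A < 1`: some ACTH secretion always
  remains. The very steep Hill factor (`gamma_A` about 21) makes the
  ACTH response an almost switch-like function of delayed glucose near
  `IC50_A`.
* **Cortisol** — secretion stimulated by ACTH:
  `m = 1 + Emax_C * H(ACTH; EC50_C, gamma_C)`.

Pool (two-compartment) alternatives — an extravascular pool filled by
zero-order synthesis and emptied by first-order transfer, with the
glucose/insulin (or ACTH) effect placed either on the synthesis or on the
transfer — are implemented as `model_variant(structure = ...)` for model
comparison, as is the rejected multiplicative glucagon inhibition.

**Steady-state closure.** Secretion rates are not free parameters. Each
`k_secr` is derived from the baseline concentration, the removal rate and
the fasting value of the modifier so that the system starts at rest under
the individual's fasting glucose and insulin
(`baseline_secretion()`); this is why fasting values are required inputs
for every individual. A fasting modifier of exactly zero secretion
(complete inhibition at baseline) is rejected as degenerate.

## Parameters, variability and covariates

`hormone_params()` carries the typical values of the final model: baselines
(glucagon 8.35 pmol/L, ACTH 2.94 pmol/L, cortisol 207 nmol/L), removal
rates (about 0.06-0.07 /min, i.e. 10-11 min half-lives), potencies
(glucose on glucagon 2.91 mmol/L with Hill 5.26; insulin on glucagon
5.51 uU/mL; glucose on ACTH 2.85 mmol/L with Hill 20.9; ACTH on cortisol
6.90 pmol/L with Hill 1.29), the maximal effects (`Imax_A` 0.941,
`Emax_C` 41.8), the glucose-delay half-life 8.68 min, proportional
residual errors (33.8% / 38.1% / 29.3%), and the BLQ inflation factor
2.01.

Between-subject variability is log-normal on the baselines and potencies,
between-occasion variability on the baselines only, both specified as CVs;
the log-scale SD is `sqrt(log(1 + CV^2))` by default (the CV-as-SD
convention is available via `cv_as_sd = TRUE`, since reported CVs are
compatible with either reading).

Insulin sensitivity enters through `GIR_20-60min`, the glucose infusion
rate per kg lean body mass during minutes 20-60 of normoglycemia (high =
sensitive). Two exponential covariate relationships are part of the final
model, both referenced to GIR = 8.13 mg/kg-LBM/min:
`IC50_I(gir) = 5.51 * exp(-0.157 (gir - 8.13))` and
`IC50_A(gir) = 2.85 * exp(-0.0155 (gir - 8.13))`. The exponential form is
used (rather than a linear one) because it keeps potencies positive over
the full covariate range and reproduces the published suppression
thresholds to their printed rounding; the linear form remains available
as a screening candidate in `scm()`.

## Derived thresholds

Because the effect functions are closed-form, the clinically interpretable
thresholds are algebraic inversions, not simulations:

```{r thresholds}
# glucose for 90% ACTH inhibition: sensitive (GIR 12.0) vs resistant (4.5)
glucose_for_acth_inhibition(0.9, gir = c(12.0, 4.5))
# 50% ACTH response occurs exactly at the covariate-adjusted IC50
glucose_for_acth_half_response(c(12.0, 4.5))
# insulin for 90% glucagon suppression at normoglycemia
insulin_for_glucagon_inhibition(0.9, g = 5.0, gir = c(12.0, 4.5))
```

Conventions: "x% inhibition" refers to the value of the Imax function
itself; "50% response" means secretion halfway between its suppressed and
unsuppressed asymptotes, which for a sigmoidal Imax model occurs exactly
at the (covariate-adjusted) IC50. Targets at or above `Imax_A` are
unattainable and return `NA`. The representative GIR values 12.0 and
4.5 mg/kg-LBM/min stand for the insulin-sensitive and insulin-resistant
quartiles of the pooled cohort; the ACTH thresholds vary by under 3%
across each quartile's plausible span. The insulin thresholds for
glucagon reproduce the published *ordering* (resistant needs more
insulin) but not the published magnitudes, which are not recoverable from
the typical parameters alone; they presumably reflect individual-level
posterior estimates.

## What the synthetic data emulate — and what they do not

The study data are not public, so `generate_dataset()` produces a fully
synthetic stand-in:

* **Covariates** (`sample_covariates()`): a Gaussian copula matched to the
  cohort's marginal medians/IQRs (GIR, BMI, fasting glucose and insulin,
  age, body fat, waist/hip, HbA1c) and to the reported rank correlations
  of GIR with BMI (-0.56) and HOMA-IR (-0.69). HOMA-IR is derived as
  `glucose * insulin / 22.5` from the sampled fasting values, so its
  median is about 2.45 rather than the tabulated 2.68 — the printed
  marginal medians are not jointly consistent, and the fasting values are
  the ones the model actually consumes.
* **Designs** (`clamp_design()`): the three hypoglycemic arms (normo 5.0
  for 60-110 min, hypo 2.7 held up to 105 min, 30-min recovery; one arm
  descends stepwise) and the hyperglycemic arm (30-min isoglycemia, then
  +3/+6/+9 steps of 45 min). Glucose is sampled every 5 min; hormones
  every 15 min (the reported sampling interval is 15-30 min; the exact
  per-study grids are only partly documented, so the 15-min grid is a
  preset, not ground truth).
* **Forcing** (`make_forcing()`): glucose approaches each phase target
  exponentially (10-min time constant) with 0.1 mmol/L measurement
  jitter; insulin rises to a clamp plateau (default 60-120 uU/mL, scaled
  by the individual's insulin-resistance index — infusion rates and
  achieved insulinemia are not published, so the plateau is a
  configurable assumption spanning the reported 0.8-580 uU/mL observation
  range) and decays after the infusion stops; in the hyperglycemic arm
  insulin rises endogenously with glucose. Profiles enter the ODEs as
  piecewise-linear interpolants (a step-function dialect is available).
* **Observation model**: proportional error `DV = f (1 + sigma eps)` with
  negative draws redrawn; records below the limit of quantification keep
  their value and are flagged (`BLQ = 1`), matching the inflated-error
  treatment rather than censoring. The LOQ defaults (glucagon 1.5 pmol/L,
  ACTH 1.1 pmol/L, cortisol 80 nmol/L) are assumptions — the sources show
  the limits only graphically.

Limits of the emulation: there is no physiological glucose-insulin
feedback (forcing is imposed, as in a clamp), no circadian rhythm, no
cortisol-to-ACTH feedback, no insulin secretion model, and the residual
noise is Gaussian. One consequence worth stating: with the published
variability magnitudes, the *tails* of the synthetic records extend
beyond the observed min-max spans of the real cohort (a finite sample's
extremes sit near the ~99th percentile of a log-normal-tailed model), so
the generator's range property is that the overwhelming majority — not
99% — of quantifiable records fall inside the observed spans. Passing
tests therefore demonstrate internal consistency of the model machinery,
not that the generator is distributionally identical to the study data.

## Estimation

`neg2loglik()` implements the Gaussian proportional-error likelihood: a
record contributes `ln 2 pi + ln sigma_i^2 + (y - f)^2 / sigma_i^2` with
`sigma_i = sigma * f`, inflated by `f_add` for BLQ records. `fit_submodel()`
minimizes it per sub-model in naive-pooled mode (the covariate model is
applied per subject; random effects are not integrated — sufficient for
recovering fixed effects from BSV-free synthetic data, and orders of
magnitude cheaper than a full mixed-effects approximation, which this
package deliberately does not reproduce). Positive parameters are searched
on the log scale, bounded fractions (`frac`, `Imax_A`) on the logit scale,
covariate slopes untransformed; Nelder-Mead with `reltol 1e-8`, multi-start
(default 5: the supplied start plus jittered restarts, SD 0.2 on the
transformed scale), best OFV wins with lexicographic tie-break. Nested
models are compared by the likelihood-ratio test at alpha 0.05, non-nested
by AIC; standard errors come from a 200-replicate subject-level bootstrap;
`scm()` runs forward inclusion at 5% and backward elimination at 1%.

Two protocol details for refitting *synthetic* data deserve emphasis:

* `f_add` is fixed at 1, because the generator draws homoscedastic
  proportional noise; fitting with the inflation active down-weights
  exactly the most-suppressed (BLQ-flagged) glucagon records and biases
  the insulin potency upward by around 10%.
* In the cortisol sub-model, `Emax_C` and the `+1` baseline term lie on a
  likelihood ridge under clamp-range ACTH (as `Emax` grows, the
  steady-state normalization `k_secr = Cort0 k_out / m(fasting)` cancels
  it), and `gamma_C` trades off against `EC50_C`. The recovery protocol
  therefore fixes `Emax_C` and `gamma_C` at their typical values and
  estimates the potency and residual error, with the ACTH driver given by
  the model prediction (ACTH sub-model at typicals), not by the noisy
  ACTH observations.

A structural fact uncovered by the model-comparison tests: when the pool
transfer rate is estimated, the pool-with-effect-on-secretion model
collapses to its infinite-pool boundary, where modulated first-order
release from an unbounded pool is exactly modulated zero-order secretion —
the turnover model is nested at that boundary. The comparison between the
two structures is therefore made both at a finite, physiologically scaled
pool (transfer rate 0.1/min, where the pool model fits clearly worse) and
by AIC when the rate is free (equal fit, one wasted parameter).

## Numerical choices

* **Simulation** (`simulate_individual()`): default integrator is lsoda
  (stiff-capable, adaptive) at `rtol 1e-8` / `atol 1e-10`. The estimation
  loop instead uses an exponential-integrator on a uniform 1-min grid —
  the exact solution of the linear turnover ODE with the secretion input
  taken piecewise-linear between nodes, evaluated blockwise so growing
  exponentials stay below `exp(30)`. The two routes agree to well below
  0.1% on the clamp designs, which the test suite asserts; tightening
  lsoda's tolerances tenfold changes trajectories by less than 0.1%.
* **Hill evaluation**: `1 / (1 + exp(gamma (ln s50 - ln s)))`, which keeps
  `H(s50) = 0.5` exact, handles `s = 0` without branching and cannot
  overflow at `gamma` beyond 20; at extreme steepness the value rounds to
  1 by floating-point underflow of `(s50/s)^gamma`.
* **Forcing interpolation**: linear between knots, constant beyond them;
  the step dialect is left-continuous at a knot (the incoming segment's
  value).
* **Degenerate inputs**: complete fasting inhibition raises a
  degenerate-baseline error; output times outside the forcing support
  raise an interpolation-range error; non-positive predictions abort the
  likelihood with the offending subject and occasion identified.

## Problem sizes

The recovery study simulates 32 subjects with GIR uniform on
3-14 mg/kg-LBM/min, one hypoglycemic plus one hyperglycemic occasion each
(about 28 observations per hormone per subject), BSV/BOV off, and the
published residual CVs. A single such replicate leaves ~5-6% sampling
error on the insulin potency (consistent with the ~11% relative standard
error reported for that parameter in the original analysis), which
cannot reliably resolve a 10% recovery band;
the protocol therefore refits replicate datasets (five in
`scripts/acceptance.R`, three in the test suite) and reports the median.
Visual predictive checks use 1000 simulation replicates; the covariate
screen's power check uses 100 subjects; the bootstrap default is 200
replicates (scaled down in tests); the type-I calibration of the LRT uses
200 small simulated null datasets.

## Known limitations

Naive-pooled estimation recovers fixed effects but not variance
components; the Laplace-type mixed-effects machinery of the original
analysis is out of scope. Circadian rhythm is absent (all source data
were collected in the morning), so whole-day simulation is outside the
model's domain. The published glucagon insulin-suppression magnitudes
(as opposed to their ordering) and all data-specific objective-function
differences are not reproducible from typical parameters and are treated
as directional checks only. The reported fasting ACTH inhibition interval
(95.51-95.53%) exceeds `Imax_A = 0.941` and cannot follow from the final
model's own equation; it is documented, not imitated.
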