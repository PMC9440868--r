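---
title: "Dose-response modelling of LDL-C lowering by bempedoic acid and statins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response modelling of LDL-C lowering by bempedoic acid and statins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldlemax)
```

## The modelling problem

Statins and bempedoic acid both lower LDL cholesterol through the hepatic
cholesterol-synthesis pathway — statins at HMG-CoA reductase, bempedoic
acid two steps upstream at ATP citrate lyase. Because they act in series
on the same pathway, their combined effect cannot be assumed additive.
This package implements a dose–response (not concentration–response)
framework that quantifies each drug's effect, their interaction, and the
clinical consequences: how much LDL-C lowering a given
statin + bempedoic acid combination buys, and what fraction of a patient
population it carries below the 100 and 70 mg/dL treatment targets.

## Model structure

**Single drug.** The fractional lowering at dose $D$ is
$E(D) = E_{max} D^h / (ED_{50}^h + D^h)$. Internally all effects are
positive fractions of baseline lowered; the clinical reporting convention
(negative percent change) is applied only at the edges by
`percent_change()`. This sign choice keeps the interaction algebra free
of double negatives. Bempedoic acid follows a simple Emax model
($h = 1$); a sigmoid variant is estimable (`fit_spec(free_hill = TRUE)`)
but on data generated with $h = 1$ its confidence interval covers 1, which
is exactly the diagnostic that justifies the simple model. The four
statins share $E_{max} = 0.787$ and $h = 0.451$ and differ only in
$ED_{50}$; these values, like every fixed quantity below, ship in
`inst/extdata/model_parameters.yaml` and load through
`model_parameters()`.

**Combination.** Two fractional effects combine as
$E_{tot} = E_a + E_b + \gamma E_a E_b$ with $\gamma = -1.35$. The form is
the only single-parameter bilinear rule we found consistent with all
fourteen published combination predictions: the package's test suite
checks every cell to within one percentage point and demonstrates that
the pure-additive ($E_a + E_b$) and pure-multiplicative
($\gamma = -1$) alternatives each miss at least four cells by more than
two points. $\gamma < -1$ means slightly *less* than multiplicative
independence, consistent with the upstream/downstream pathway coupling.
$E_{tot}$ is clamped to $[0, 1)$ so simulated concentrations can never go
negative; with the shipped parameters the clamp is never active except
under extreme variability draws.

**Turnover.** LDL-C follows the indirect-effect model
$dL/dt = k_{in}(1 - E_{tot}) - k_{out} L$ with $k_{out} = 0.01\,h^{-1}$
fixed (it is not identifiable from steady-state data) and
$k_{in} = k_{out} \cdot baseline$ derived. At week 12 (2016 h) the
transient term $e^{-k_{out} t} \approx 2\times10^{-9}$, so all week-12
machinery uses the steady state $baseline(1 - E_{tot})$; the closed-form
time course `ldl_timecourse()` exists for trajectory plots and is verified
against an independent ODE solution in the tests.

## Population simulation

`draw_subjects()` draws individual baselines log-normally with median
equal to the typical value and $\mathrm{sdlog} = \sqrt{\log(1 + CV^2)}$.
Two variability conventions matter:

* the **monotherapy population** (baseline 147.1 mg/dL, CV 23.0%) also
  carries a log-normal multiplier on the bempedoic acid $E_{max}$
  (CV 36.2%), the standard pharmacometric parameterisation for a
  positive bounded effect;
* the **combination populations** (statin-specific baselines
  177.9/160.4/171.9/156.7 mg/dL) carry baseline variability only — the
  published combination models report no $E_{max}$ variability, and the
  printed simulated means are only reproduced without it.

Cross-statin comparison tables (absolute LDL-C, goal attainment) put all
statins on the atorvastatin-model baseline distribution (median 177.9,
CV 27.1%), the highest-baseline population, so columns are comparable;
the same 1000 baseline draws are reused across all conditions (common
random numbers), so differences between cells are pure drug effect.
Residual error — observation = $f(1 + \varepsilon_{prop}) +
\varepsilon_{add}$ — is excluded from prediction summaries, which
describe model-predicted LDL-C, and included when the generator emits
observation-level datasets for estimation.

With 1000 subjects the Monte-Carlo standard error of a mean LDL-C cell is
about 1.6 mg/dL at baseline and shrinks proportionally with
$(1 - E_{tot})$; predicted means are reproducible to roughly ±2.5 mg/dL
across seeds, which is the tolerance the acceptance checks use.

## Uncertainty

`parametric_bootstrap()` resamples non-fixed parameters from independent
normal sampling distributions (e.g. $ED_{50} = 44.0$, SE 3.8); fixed
parameters are held constant. `nonparametric_bootstrap()` resamples whole
subjects with replacement, keeping each subject's records together. The
90% intervals reported by `summarize_condition()` and the stochastic
`table3_report()` are empirical 5th–95th percentiles of
bootstrap-replicate means — percentile rather than normal-approximation
intervals, chosen for robustness since replicate distributions of
ratio-type quantities are mildly skewed. The intervals published for the
statin-alone columns derived from refitting the original pooled
subject-level data, which are not redistributable; with all statin
parameters fixed without error, those intervals are reported as `NA`
rather than fabricated, and the corresponding published bounds are
covered by property-based tests only.

## Pre-statin baseline imputation

Combination-study patients enrol already on a stable statin, so their
entry LDL-C is an on-statin value. `impute_prestatin()` inverts the
statin model: deterministically $B = L_{obs} / (1 - E(dose))$, which
round-trips exactly and is the reference behaviour. Stochastic mode
acknowledges that individual statin responses vary: the fractional effect
is perturbed by a log-normal multiplier (default CV 30%, configurable)
truncated below 0.95 with rejection, so the inversion cannot blow up. The
truncated-draw mean is validated against numerical integration in the
tests. The 30% CV is a choice, not an estimate — the original
uncertainty parameterisation is not published — which is why
deterministic mode is the default.

## Estimation

`fit_monotherapy()` maximises a marginal likelihood in which the two
subject-level random effects (log-baseline, log-$E_{max}$ multiplier) are
integrated out by a Laplace approximation: a vectorised per-subject
Newton ascent of the joint density (finite-difference curvature, damped
steps) followed by the Gaussian correction. This replaces the original
analysis's FOCE-I machinery with a documented, self-contained
approximation of the same marginal likelihood; on test datasets the
Laplace value agrees with a 40-node tensor Gauss–Hermite quadrature to
within 0.2%. Numerical choices that matter:

* parameters are estimated on transformed scales (log for positives,
  logit for $E_{max}$), so the optimizer is unconstrained and CIs mapped
  back always respect bounds;
* the outer optimizer is bounded quasi-Newton (L-BFGS-B) from
  `n_starts = 3` seeded starts (first data-driven, rest jittered), with
  finite-difference step $10^{-4}$ — deliberately far above the
  $\sim10^{-5}$ numerical noise floor that warm-started inner
  optimisations leave on the objective — and a relative-objective
  tolerance of about $2\times10^{-8}$;
* standard errors come from the inverse Hessian evaluated with a frozen
  warm start, making that objective exactly deterministic; convergence is
  declared by positive-definite curvature rather than by the raw
  optimizer code, which near the noise floor is conservative;
* non-finite parameter regions return a large penalty (not an error), and
  a design with fewer than three bempedoic acid dose levels raises a
  structured `ldlemax_unidentifiable` error since $ED_{50}$ is then
  meaningless.

$\gamma$ is deliberately not freely estimated. Mirroring the published
sensitivity-analysis strategy, `profile_gamma()` fixes every other
parameter at its fixture value and evaluates the combination likelihood
on a grid (default $-3$ to $0$ by $0.05$), returning the profile curve
and its minimiser. On synthetic combination data of 2000 subjects the
minimiser lands within ±0.15 of the generating $-1.35$.

## The synthetic-data generator

The original pooled dataset (14 studies, data on file) is not available;
`generate_trial()` emulates its statistical structure: log-normal
baselines, monotherapy $E_{max}$ variability, combined residual error,
dose-ranging monotherapy arms, and combination arms whose entry visit is
an on-statin baseline (statin effect already expressed) so the imputation
stage sees realistic input. Study labels are cosmetic — no study-level
random effect is simulated, matching the model actually fitted, which
pools across studies. The monotherapy dose grid is not published;
the `monotherapy_dose_ranging` preset uses 0/60/120/180/240 mg
(200/arm) to bracket the therapeutic 180 mg dose, and because its lowest
active dose already exceeds $ED_{50} = 44$ mg, the `monotherapy_rich`
preset adds a 20 mg arm (167/arm, ~1000 subjects total) for
parameter-recovery work. Presets are pure functions; every stochastic
path is reproducible from a single seed.

What passing tests on these data do **not** show: robustness to dropout,
titration, adherence, study heterogeneity, covariate effects, or
model misspecification — none of which the generator emulates. The
recovery results certify the estimator against its own generating model,
not against real trial complexity.

## Problem sizes and runtime

Prediction tables use 1000 subjects per condition (the published
simulation size). The recovery study in the acceptance suite runs 20
replicates of ~1000 subjects (single data-driven start per replicate,
standard errors skipped) plus a 61-point $\gamma$ profile on 2000
subjects; the full test suite completes in a few minutes on one CPU.

## Known limitations

* Week-12 steady-state algebra only; no longer-term extrapolation, no
  pharmacokinetics (dose–response, not concentration–response), and
  bempedoic acid doses far from 180 mg carry extra uncertainty since the
  combination data cluster there.
* The one-cell discrepancy of the absolute-LDL-C table at
  pravastatin 10 mg alone (~2.6 mg/dL) traces to an internal
  inconsistency between the published percent-change and absolute tables
  for that condition, not to a reproducible model choice; the acceptance
  suite documents it rather than absorbing it into a wider tolerance.
* No ezetimibe or PCSK9-inhibitor effects; no covariate modelling.
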