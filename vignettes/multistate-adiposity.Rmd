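---
title: "Multistate life tables for adiposity and CVD-free life expectancy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate life tables for adiposity and CVD-free life expectancy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`adipolife` estimates how composite adiposity — body-mass index (BMI)
combined with waist circumference (WC) — relates to the number of years
middle-aged adults can expect to live free of, and with, cardiovascular
disease (CVD). This vignette documents the model, the tunable parameters,
what the synthetic-cohort generator does and does not emulate, the
numerical choices, and the limitations a user should know about before
trusting the output.

## The illness-death model

The analysis treats each participant as moving through three states:
free of CVD (1), living with CVD (2), and dead (3), with transitions
1→2 (incidence), 1→3 (death without CVD) and 2→3 (death with CVD). No
recovery is allowed, and only the first CVD event counts. Each
cause-specific transition hazard is Gompertz in attained age `a`:

    h_t(a) = lambda_t * exp(gamma_t * (a - 50)) * exp(x' beta_t)

with `lambda_t` the rate at the reference age 50, `gamma_t` the
log-linear age slope, and `beta_t` log hazard ratios for the exposure
categories and confounders. The Gompertz form is the conventional model
for adult mortality and CVD incidence, whose rates rise roughly
exponentially with age; a Weibull alternative (`fit_weibull()`) is
provided purely for model-fit comparison by AIC.

## Exposure phenotyping

Composite adiposity is the 3x3 grid of WHO BMI classes (normal < 25,
overweight 25 to < 30, obesity >= 30 kg/m²) against WHO WC classes
(healthy / abdominal overweight / abdominal obesity, cut at 94 and
102 cm in men, 80 and 88 cm in women), collapsed to four categories.
The published material defines the collapse only graphically, so the
mapping used here was reconstructed from the arithmetic of the
single-measure marginals: `very_high` is BMI obesity at any WC (matches
the obesity marginal in both sexes), `high` is abdominal obesity below
BMI 30 (abdominal-obesity marginal minus obesity), `increased` is
abdominal overweight below BMI 30 or overweight with a healthy WC, and
`low` is the doubly-healthy cell. This reproduces the published
composite prevalences within about one percentage point in both sexes.
The discordant normal-BMI/abdominal-obesity phenotype lands in `high`;
that cell cannot be verified from the text and is exposed as a
configurable mapping (`adiposity_mapping()`) so an alternative reading
can be swapped in.

## Estimation pipeline

1. **Person-time.** Follow-up is split at every measurement wave (where
   exposure updates, carried forward between waves) and into 1-year
   attained-age intervals (`build_person_time()`, `step` tunable).
   Disease-free time feeds transitions 1→2 and 1→3 simultaneously;
   post-CVD time feeds 2→3. Participants without any valid exposure
   measurement are dropped (complete case). Same-age CVD and death is
   resolved as CVD followed by a one-day diseased sojourn, so fatal
   first events count as both incidence and CVD death.
2. **Transition models.** `fit_gompertz()` maximises the Poisson
   person-time likelihood with a linear attained-age term — the standard
   piecewise operationalisation of Gompertz proportional hazards. The
   event part of each row's likelihood is evaluated at the exact event
   age (equivalently: event rows are split into a censored exposure
   piece plus an epsilon-duration event row), which makes the estimates
   agree with the direct Gompertz survival MLE to better than 1e-3 at
   1-year splitting; with midpoint evaluation the agreement would
   degrade to about 1% through a small slope bias. Uncertainty comes
   both model-based and cluster-robust (per-individual sandwich with the
   `G/(G-1)` small-sample factor); Wald 95% CIs are formed on the log
   scale. Hazard-ratio models adjust for the pre-specified baseline
   confounders (age, household composition, education, physical
   activity, diet score, smoking with cigarettes/day in current smokers,
   alcohol, COPD), all held at baseline; exposure alone is time-varying.
3. **Prevalence calibration.** Overall (marginal) rates are converted to
   category-specific rates through the identity
   `r_overall(a) = sum_c p_c(a) HR_c * r_ref(a)`, with `p_c` the
   observed category prevalences per sex, 10-year age band and CVD
   status (step functions over the band, no interpolation; empty cells
   borrow the nearest band, flagged). The prevalence-weighted average of
   the category rates reproduces the overall rate identically, which is
   asserted to 1e-12 in the tests.
4. **Life table.** `build_lifetable()` runs the three-state cohort life
   table from age 50 to 80 in 1-year intervals with rates constant
   within an interval. Closure at 80 is plain truncation: expectancies
   are *temporary* life expectancies over [50, 80) and should not be
   compared with open-ended LE figures. Disease-free LE and LE with CVD
   are the time-integrals of the two living states; their sum is total
   LE by construction.
5. **Uncertainty.** `bootstrap_le()` redraws all Gompertz parameters and
   log hazard ratios from their robust-covariance normal approximations
   (independently per transition — no cross-transition covariance is
   estimable from separately fitted models), redraws prevalence vectors
   as Dirichlet with observed cell counts (a flag isolates regression
   uncertainty), rebuilds every life table per draw, and reports
   percentile 2.5/97.5 intervals; 1,000 iterations by default.

## Within-interval accounting

With rates constant within a 1-year interval the three-state chain has a
closed-form solution, including the path disease→death inside a single
interval. The default (`method = "exact"`) uses that kernel for both
occupancy updates and person-years, so the life table matches a
continuous-time microsimulation on the same rates up to Monte-Carlo
error — `microsimulate_le()` is shipped precisely to make that check
routine, and the test suite runs it at 10^6 trajectories. The classical
discrete flow with half-interval (trapezoid) crediting is kept as
`method = "discrete"`; at cohort-scale rates the two differ by a few
hundredths of a year, the discrete method's bias being of order `q12*q23` per
interval. The reported per-interval transition probabilities `q12`,
`q13`, `q23` use the conventional competing-risk apportionment under
either method.

The starting state at age 50 is configurable: the default seeds each
category's table with its observed CVD prevalence in the 50-59 band
(`init = "observed"`); `init = "healthy"` starts everyone disease-free,
which is the cleaner choice for simulation experiments where the truth
is computed from the generating hazards.

## The synthetic cohort generator

No public version of the underlying cohort exists, so
`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes:

* **Anthropometry** is bivariate log-normal in (BMI, WC) per sex with a
  Gaussian copula; height is drawn separately and weight back-solved, so
  BMI is exactly weight/height². The log-normal parameters are
  quantile-matched to the published baseline BMI and WC class
  frequencies (e.g. men: P(BMI<25) = 0.253, P(BMI<30) = 0.837), which
  lands the composite categories within ~1 point of the published
  distribution without further tuning. The default log-scale correlation
  is 0.872, calibrated so the *pooled* two-sex Pearson correlation
  between BMI and WC is 0.81 — pooling attenuates the within-sex
  correlation because the sexes differ in mean WC.
* **Events** are drawn from the configured Gompertz hazards by
  inversion, piecewise over the wave intervals so the hazard follows the
  participant's current category as anthropometry drifts (a small
  correlated log-scale random walk, 0.0015/year drift, 0.010/sqrt(year)
  SD). Post-CVD mortality restarts on the attained-age clock (Markov);
  whether mortality after CVD depends on time since diagnosis is not
  stated in the source material, so the Markov choice is an assumption
  of this package, matching the age-indexed life table.
* **Default conditions** mirror the study: 2,323 eligible participants
  plus 114/128/1 exclusion-flagged extras, 49.8% women, entry ages
  50-72 weighted 59/39/2% across 10-year bands, five waves five years
  apart, 22 years of administrative censoring, and true hazard ratios
  set to the published adjusted estimates. Baseline reference-category
  hazards (e.g. men 1→2: 0.0040/year at 50, slope 0.070/year) were
  calibrated once, by simulation at 10x scale, to reproduce the
  published totals of ~695 incident CVD events and ~587 deaths; the
  defaults land within ~2%.
* **Covariates and biomarkers** are drawn per sex from the published
  baseline table's margins (education, activity, smoking, alcohol, diet
  score, COPD, blood pressure, glucose, lipids), independent of exposure
  by default. A `confounding` knob ties the latent adiposity propensity
  to a lifestyle risk score that is linear in the smoking and activity
  dummies, and `covariate_log_hr` lets that score enter the true
  hazards — together they create a correctly-specified confounded regime
  for testing adjustment. A `missing_anthro` knob reproduces the ~10%
  (men) / 6% (women) complete-case exclusions.

What the generator does **not** emulate: recruitment and wave
non-response, registry linkage and diagnosis coding (events are labelled
directly), item-level diet data, within-person biomarker trajectories,
and any frailty or unmeasured heterogeneity. Passing tests therefore
demonstrate that the estimation machinery is correct under the model's
own assumptions — not that those assumptions hold in any real cohort.

## Numerical choices

* Poisson-Gompertz optimisation: Newton iterations with step-halving,
  relative log-likelihood tolerance 1e-9, 200-iteration cap,
  deterministic start at the exponential occurrence/exposure fit; no
  randomness anywhere in estimation.
* Categories with zero events are flagged (`zero_event_categories`) and
  a ridge fallback guards the Newton solve near separation.
* Non-PSD covariance draws are repaired to the nearest PSD matrix with a
  warning; bootstrap draws producing invalid rate sets are redrawn and
  counted (`n_invalid`).
* All ages are written to output files at 2-decimal precision; missing
  values are empty fields.

## Problem sizes used by the test suite

The suite exercises the pipeline at the sizes the package's own
validation experiments use: hazard-ratio recovery on single-sex cohorts
of 50,000; microsimulation cross-checks at 10^6 trajectories per
category; and a nested coverage experiment of 200 replicates at
n = 5,000 with 250 bootstrap iterations each, checking that the 95%
interval for the very-high-vs-low difference in CVD-free LE covers the
generating truth at close to nominal rate. `scripts/coverage_experiment.R`
reruns that experiment standalone with configurable sizes.

## Limitations

* Temporary LE over [50, 80) by construction; absolute values depend on
  the closure convention and are smaller than open-ended LE.
* The composite-category mapping for the discordant
  normal-BMI/abdominal-obesity cell is a reconstruction, not a quote;
  swap the mapping if better information is available.
* Baseline-fixed confounders and carried-forward exposure mean the
  usual caveats about time-varying confounding apply.
* The bootstrap treats transitions as independent and parameters as
  asymptotically normal on the log scale; with very few events per
  category the percentile intervals inherit that approximation.
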