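---
title: "Methods: latent class HbA1c trajectories and heart failure risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent class HbA1c trajectories and heart failure risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the synthetic data generator,
the numerical choices and the design decisions behind **hba1ctraj**. Code
chunks are illustrative and not evaluated when the vignette is built; the
README contains a fully worked, executed example.

## 1. Scientific setting

People newly diagnosed with type 2 diabetes differ not only in their average
glycaemic control but in the *shape* of their HbA1c trajectory over the first
years after diagnosis. The package models longitudinal HbA1c measurements,
timed from the date of diabetes diagnosis (DDD), as a finite mixture of
latent trajectory classes and then asks whether class membership predicts the
time to a first hospitalization for heart failure (HHF), over and above
demographics and pre-existing complications.

The analysis pipeline has five stages:

1. **Synthetic registry generation** — emulates a hospital diabetes registry
   (measurements, subject demographics, event records) with known ground
   truth, so every estimator can be validated against the generating model.
2. **Cohort construction** — DDD imputation, eligibility filtering, and
   re-basing of all measurement times to weeks since diagnosis.
3. **Latent class growth analysis (LCGA)** — multi-start EM over a grid of
   time-link shapes and class counts, selected by BIC plus a minimum class
   size rule.
4. **Survival analysis** — Kaplan–Meier curves per class, log-rank tests,
   and a multivariate Cox proportional hazards model, all implemented from
   first principles in this package.
5. **Sensitivity and validation** — baseline-shift re-grouping, DDD
   re-seeding stability, and split-sample predictive validation.

## 2. The latent class growth model

For subject $i$ with measurements $y_{ij}$ at times $t_{ij}$ (weeks since
diagnosis), the model is a $K$-component mixture of fixed-effect growth
curves:

$$
f(y_i) = \sum_{k=1}^{K} \pi_k \prod_{j} \phi\!\big(y_{ij};\,
  x(t_{ij})^\top \beta_k,\, \sigma\big),
$$

where $x(t)$ is a time-link basis, $\beta_k$ the class-specific curve
coefficients, $\pi_k$ the mixing proportions, and $\sigma$ a residual
standard deviation **shared across classes**. The *subject* is the mixing
unit: conditional on class, a subject's measurements are independent
Gaussians around the class curve. This is LCGA in the strict sense — there
are no subject-level random effects, so within-class heterogeneity is
absorbed entirely by $\sigma$.

### Time-link bases

Five shapes are supported (`basis_spec()`), with time $t$ in weeks and
$s = t/100$ (the `time_scale` keeps polynomial design columns well
conditioned):

| shape | $x(t)$ | dimension |
|---|---|---|
| linear | $(1, s)$ | 2 |
| quadratic | $(1, s, s^2)$ | 3 |
| cubic | $(1, s, s^2, s^3)$ | 4 |
| logarithmic | $(1, \log(t+1))$ | 2 |
| exponential | $(1, e^{-t/26})$ | 2 |

The logarithmic link uses raw weeks (with $+1$ so the intercept is the value
at diagnosis); the exponential time constant defaults to 26 weeks (about six
months, the time scale on which initial treatment changes act) and is
configurable via `exp_timescale_weeks`.

### Estimation

`fit_lcga()` maximizes the mixture likelihood by EM:

- **E-step**: per-subject posterior class probabilities computed on the log
  scale with a log-sum-exp reduction, so long measurement series cannot
  underflow.
- **M-step**: per-class weighted least squares for $\beta_k$ (weights =
  posteriors), a pooled residual variance
  $\sigma^2 = \sum_{i,k} p_{ik} \|y_i - X_i\beta_k\|^2 / N$ floored at
  $10^{-12}$, and closed-form mixing proportions. The proportions are stored
  as logits relative to the last class so that serialized parameters
  round-trip exactly.
- A weighted design that is numerically rank-deficient raises a classed
  error (`hba1ctraj_rank_error`) naming the offending class rather than
  silently producing garbage.

Convergence is declared when the relative log-likelihood change falls below
`tol` ($10^{-6}$ by default, relative to $|\ell| + 10^{-3}$).

### Multi-start strategy

Mixture likelihoods are multi-modal, so `fit_lcga()` uses a deterministic
multi-start scheme seeded by `seed`:

1. Start 1 is a $k=1$ least-squares fit whose intercept is offset by ordered
   normal quantiles scaled by the residual SD — a "spread the classes
   vertically" start that is often already close to the dominant mode.
2. Starts $2,\dots,n_\text{starts}$ perturb start 1 with Gaussian noise
   scaled to each coefficient column's dispersion.
3. Every start is run for a short burn-in (30 iterations by default); only
   the best burn-in survivor is refined to full convergence.

Burn-in traces for every start and the refinement trace are returned
(`burn_trace`, `trace`) and are checked to be monotone in the test suite.
Fits are bit-reproducible for a given seed, and the class labels are
canonicalized by **descending mean fitted HbA1c**, so class 1 is always the
highest trajectory and class $K$ the lowest. The lowest class is the default
reference in all downstream survival contrasts.

### Model selection

`select_lcga_model()` scans all shapes × $k = 1..k_\text{max}$ and applies a
two-part rule:

- a grid cell is *admissible* when its smallest modal class holds at least
  `min_prop` (3%) of subjects — tiny classes are unstable and clinically
  uninterpretable;
- the chosen $k$ is the largest value at which **all** shapes are still
  admissible while some shape breaks the floor at $k+1$;
- the chosen shape minimizes BIC at that $k$.

BIC is computed on the **number of subjects**, not the number of
measurements: $\mathrm{BIC} = -2\ell + p \log n_\text{subjects}$ with
$p = K d + (K-1) + 1$ free parameters ($d$ basis columns per class, $K-1$
mixing logits, one $\sigma$). Subjects are the independent sampling units in
LCGA, so measurement-level $n$ would overweight densely sampled subjects.

A warm-start $k$-fold cross-validated held-out log-likelihood per grid cell
is recorded as corroboration; it never overrides the BIC + proportion rule.
Warm-starting each fold from the full-data parameters keeps the whole grid
affordable.

Class separation diagnostics: `appa()` (average posterior probability of
assignment among modally assigned subjects, per class) and
`scaled_entropy()` ($1 - \sum_{ik} -p_{ik}\log p_{ik} / (n \log K)$, 1 =
perfect separation).

## 3. The synthetic registry generator

`default_registry_config()` encodes a five-class population with
logarithmic mean curves. The defaults are fixed study conditions, not tuning
knobs:

- class shares ≈ 0.355 / 0.411 / 0.034 / 0.107 / 0.092 (rescaled to sum
  to 1), baseline HbA1c 6.23 / 7.16 / 10.6 / 7.69 / 8.73%, with
  gentle-to-steep log-time declines so the highest classes improve fastest;
- a **common residual SD of 0.55%**: the generating model matches the
  fitted model's shared-$\sigma$ assumption so that recovery tests have a
  well-defined truth. Real registries show class-specific dispersion; this
  is a deliberate simplification, not a claim about data;
- **constant (exponential) HHF hazards per class**, calibrated in closed
  form so that the cumulative incidence at each class's mean follow-up time
  matches its target (e.g. 1.43% at 239.9 weeks for the healthiest class);
  the proportional-hazards assumption therefore holds exactly by
  construction. Optional `covariate_log_hr` terms (e.g. an age effect) can
  scale the hazard, but by default the covariates do **not** feed the
  hazard — class is the only risk factor, which makes the adjusted Cox
  model's behaviour easy to reason about;
- ~15 visits per subject (Normal(15, 5.5), truncated) over a follow-up of
  ~245 weeks (Normal(245, 68)); 95% of subjects are floored to eligibility
  (≥ 5 visits, ≥ 160-week span, with a visit at the end of follow-up), the
  remainder fall where they fall, so the eligibility filter has real work
  to do;
- a 19% **diagnosis-year mismatch fraction**: for these subjects the first
  HbA1c specimen is dated a year or more after the recorded diagnosis year,
  which is exactly the situation that forces DDD imputation downstream;
- 13% of subjects have all prior-complication flags missing, exercising the
  `prior_missing` indicator in the Cox design;
- visit times are snapped to a day grid **before** the class curve is
  evaluated, so a noiseless configuration reproduces the curve exactly up
  to output formatting; administrative censoring at 364 weeks.

Event times in `events.csv` are expressed relative to the **first specimen
date** (they can be negative when the event predates the first recorded
HbA1c), mirroring how registry extracts are usually keyed to laboratory
records rather than to the — possibly unknown — diagnosis date.

What the generator does *not* emulate: visit-frequency dependence on
disease severity, treatment-driven trajectory changes, competing risks
(death), informative censoring, or measurement batch effects. Conclusions
about those phenomena cannot be drawn from this generator.

## 4. Cohort construction

`build_cohort()` turns raw tables into an analysis cohort:

- **DDD imputation** (`impute_ddd()`): when the diagnosis year equals the
  first specimen year, the DDD *is* the first specimen date; otherwise a
  day offset uniform on $\{0,\dots,364\}$ within the diagnosis year is
  drawn. The draw is deterministic per `(seed, subject_id)` via a hash of
  the subject id mixed with the seed, so imputation is independent of
  subject processing order and reproducible record-by-record; the global
  RNG state is saved and restored around the draw.
- **Eligibility**: at least 5 HbA1c measurements spanning at least 3 years
  (1095.75 days) of specimen dates. Exclusions are recorded with reasons
  (`too_few_samples`, `span_too_short`). Measurements predating the imputed
  DDD are dropped and eligibility is re-checked
  (`ineligible_after_ddd_rebase`), because a subject can lose enough early
  measurements to fall below the floor.
- **Time origin**: all measurement times become weeks since DDD.
- **Events**: a subject is an HHF case iff the recorded event lands strictly
  after the DDD; an event that predates the imputed diagnosis is treated as
  unusable and the subject is censored at the last measurement. Censoring
  defaults to the last observed measurement (`censor_at =
  "last_measurement"`); an events-table override is available when the
  registry supplies administrative censoring dates.

Provenance (raw, excluded and final counts and exclusion reasons) is carried
on the cohort object and serialized with it.

## 5. Survival estimators from first principles

The survival stack is implemented from scratch — this is a core deliverable,
not a convenience wrapper. The widely used `survival` package appears only
in the test suite as an independent oracle.

- `km_curve()` — product-limit estimator over distinct event times, with
  Greenwood-ready risk/event counts.
- `logrank_test()` — $k$-group log-rank using the hypergeometric covariance
  of the per-time event counts and a generalized inverse of the covariance
  of the first $k-1$ groups. Identical groups short-circuit to a statistic
  of exactly 0 and $p = 1$ (floating-point noise should not manufacture a
  tiny p-value from two copies of the same data).
- `cox_fit()` — Cox proportional hazards with **Efron's tie correction**,
  maximized by Newton–Raphson with step-halving. Covariates are centered
  internally for conditioning; constant columns are dropped with a warning
  naming them; a non-converged fit with runaway coefficients raises a
  classed error indicating likely separation. Wald confidence intervals and
  p-values come from the inverse observed information.
- `concordance_index()` — Harrell's C over usable pairs: pair $(i, j)$ is
  usable when $i$ has an event strictly before $t_j$; tied risk scores
  count one half. Ties in *time* are handled by the strict-inequality rule,
  which is the textbook Harrell definition and can differ in the last
  decimals from `survival::concordance` (which uses a finer tie
  partition); the test suite therefore asserts exact agreement on tie-free
  data and pairs-enumeration agreement on tied data.

## 6. Pipeline analyses and design decisions

`run_primary_analysis()` chains the stages and reports per-class KM curves,
omnibus and pairwise log-rank tests (with an observed/expected hazard-ratio
approximation per pair), and a Cox model adjusted for sex, ethnicity
(Chinese reference), age at diagnosis, prior complications (missing flags
set to 0, plus an explicit `prior_missing` indicator).

Several questions have no single right answer; the package's choices are:

- **Baseline shift** (`baseline_shift_analysis()`): measurements before the
  shift are dropped, time is re-zeroed, and the same (shape, $k$) model is
  refit. New classes are matched to the original ones by mean-curve
  distance, with the shifted curve at $t$ compared against the original
  curve at $t + \text{shift}$ — matching in the *original* time coordinates
  is what makes "the same class, seen later" the identity map. Subjects
  left with fewer than two measurements are excluded and counted. The
  regrouped-vs-original Cox contrast measures whether subjects who migrate
  into the target class import their original risk.
- **Class matching** (`match_classes()`): exhaustive minimization of summed
  squared mean-curve distance over permutations ($k \le 8$). Hungarian-style
  solvers are unnecessary at these sizes and exhaustive search is exact.
- **DDD re-seeding** (`seed_sensitivity_analysis()`): the entire cohort
  build and fit are repeated under a second imputation seed; retention is
  the fraction of common subjects keeping their matched class. Identical
  per-class survival compositions short-circuit the log-rank to 0, for the
  same reason as above.
- **Predictive validation** (`predictive_validation()`): an 80/20
  subject-level split; the LCGA and the Cox model are fit on training data
  only. Held-out subjects are assigned classes by frozen-parameter
  posterior prediction and compared against a full-data fit (retention).
  Cumulative windows of 50 weeks (7 windows) re-predict *only* the class
  assignment; the Cox coefficients stay fixed, so the window curve isolates
  how much trajectory information accrues over time. Validation subjects
  without a measurement in the first window are excluded once, because a
  window classification needs at least a baseline value. A no-class Cox
  model on the same validation subjects gives the reference concordance.

## 7. Problem sizes and numerical choices

The package's own default scales — chosen for the test suite and the
acceptance script, and comfortably within a laptop's budget — are cohorts of
2 000–2 500 subjects (~30 000 measurements), $k_\text{max} = 7$, 5–20 EM
starts. A 5-class fit on 2 000 subjects takes a few seconds; the full
selection grid with 5 starts per cell takes well under a minute.

Numerical choices worth knowing:

- all mixture arithmetic in log space with log-sum-exp;
- EM tolerance $10^{-6}$ relative; $\sigma^2$ floored at $10^{-12}$;
- polynomial bases on $t/100$ to keep $X^\top X$ well conditioned;
- log-rank covariance inverted by generalized inverse so collinear group
  margins do not abort the test;
- Newton–Raphson with step-halving (up to 30 halvings) and an explicit
  separation diagnostic for the Cox model;
- every stochastic stage takes an explicit integer seed (< $2^{31}$), and
  seeds are logged in the analysis report.

## 8. Limitations

- LCGA's fixed-effects-only assumption means within-class variance is a
  single $\sigma$; heavy subject-level heterogeneity will inflate the
  selected number of classes.
- The selection rule inherits BIC's large-$n$ conservatism and the 3% floor
  is a pragmatic stability device, not an inferential statement.
- The generator's proportional, constant hazards make the Cox model's
  assumptions true by construction; real-data violations (time-varying
  effects, competing mortality) are out of scope.
- Harrell's C is estimated without inverse-probability-of-censoring
  weighting and is therefore censoring-distribution dependent.
- The pipeline treats the imputed DDD as known when fitting; imputation
  uncertainty is explored only through the re-seeding sensitivity analysis,
  not propagated into standard errors.
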