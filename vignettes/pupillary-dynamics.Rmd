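---
title: "Pupillary dynamics in neuro-ICU coma cohorts: indices, inference and prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pupillary dynamics in neuro-ICU coma cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupildyn)
```

## The problem

In the neuro-intensive care unit, the pupils of comatose traumatic brain
injury (TBI) patients are examined at the bedside every two hours: pupil
*size* is recorded as one of five categories (isochoric, left or right
anisochoria, bilateral miosis, bilateral mydriasis) and the *light
reflex* (photo-reactivity) as one of four (bilaterally present,
bilaterally absent, unilaterally present right or left). Prognostic
scores in routine use consume only the admission examination. This
package instead treats the whole categorical time series as the object
of analysis and asks whether its *dynamics* — how often the state
switches, and how much time it spends in the normal state — predict the
dichotomized 6-month outcome (Glasgow Outcome Scale Extended, favorable
if GOSE > 4).

Four dynamical indices summarize a window of a patient's series:

* **PS-jump-rate** — number of changes of pupil-size state between
  consecutive readings, divided by the number of measurements *N*;
* **PS-isochoria-percentage** — fraction of readings in the isochoric
  (normal) state;
* **PR-jump-rate** and **PR-presence-percentage** — the same two
  statistics for the photo-reactivity series.

All four live in [0, 1]; jump rates are bounded by (*N* − 1)/*N*.

### The jump-rate denominator

The index definition divides the change count by the number of
*measurements* (*N*), not the number of transitions (*N* − 1). We
implement /*N* as the default because that is the stated definition,
and expose `denominator = "transitions"` for users who prefer the
conventional per-transition rate; with ~190 readings per patient the
two differ by under 1%.

### Window conventions

Windows are half-open `[start, end)`: a reading exactly on a boundary
belongs to the later window. The day-by-day ("ND") analysis evaluates
the indices on expanding cumulative windows `[0, 24·(ND + 1))` hours;
ND = 0 is the first day's data, so a "Day 0" model is estimable from
twelve 2-hourly readings. Missed readings contribute to neither
numerator nor denominator (complete-case within window), and a change
across a gap counts as at most one change. Jump rates are undefined on
windows with fewer than two readings and propagate as missing values,
never as zeros.

## Pre/post-sedation inference

Sedation suppresses pupillary behaviour, so each patient's series is
split at the end of analgosedation into PRE and POST segments and each
index is analysed with a 2 × 2 mixed repeated-measures ANOVA: outcome
group (favorable vs unfavorable) between subjects, period (PRE vs POST)
within subjects. Patients lacking post-sedation observations (sedation
until discharge) are excluded listwise. Sums of squares are Type II;
because the design has a single two-level within factor entered first,
these coincide with the classical univariate mixed-model decomposition,
which our tests verify against an independently coded sums-of-squares
oracle to 10⁻¹⁰. Sphericity is not an issue with only two within
levels. Exactly six post-hoc contrasts are computed per index —
between groups at PRE and at POST (pooled-variance t), PRE vs POST
within each group (paired t), and the two marginal contrasts — with
Bonferroni correction by the fixed factor 6.

Clinical covariates available only as printed group summaries (means ±
SD, category counts) are compared with the matching summary-statistic
tests: pooled-variance Student t for quantitative variables (the
pooled form is the dialect that reproduces printed group-table
statistics exactly), Yates continuity-corrected chi-square for 2 × 2
counts, and plain Pearson chi-square for larger tables such as the
Marshall CT score. The Yates statistic floors at zero when
|ad − bc| ≤ n/2.

## Day-by-day prognosis

For each ND from 0 to 10, the four indices evaluated on the cumulative
window enter:

1. **point-biserial screening** — Pearson correlation of each index
   with the 0/1 outcome (favorable = 1), two-sided p from the t
   transform, marked significant at uncorrected p < 0.05;
2. **exhaustive logistic model selection** — all 2⁴ − 1 = 15 predictor
   subsets are fitted by maximum-likelihood logistic regression and
   scored by three criteria: the likelihood-ratio test against the
   intercept-only model (model significance), BIC = k·ln n − 2·ln L
   with k = predictors + 1, and leave-one-out cross-validated accuracy
   at a 0.5 probability cutoff;
3. **ROC/AUC** — for a chosen single-index model, the ROC of the fitted
   probabilities per ND, with AUC equal to the normalized Mann–Whitney
   U statistic (ties count one half).

The LR test was chosen as the "model significance" measure (a Wald
test would be the alternative); with nested models it also supplies a
structural invariant — deviance never increases as predictors are
added — that the test suite checks across the whole grid.

### Separation

With twenty patients and strongly separating indices, complete or
quasi-complete separation of the logistic MLE is the rule rather than
the exception. We detect it (non-convergence, coefficient magnitude
above 15, or fitted probabilities pinned to 0/1), always report a
`separation_flag`, and refit by Firth-penalized logistic regression —
Newton iterations on the hat-adjusted score with step halving — which
is used *for prediction* (LOOCV folds, ROC scores). Reported BIC and
LR statistics keep the MLE likelihood at its stopping point, so a
separated model's BIC degenerates to k·ln n. Because every separating
model then has numerically indistinguishable BIC, the per-day winner is
chosen with explicit tie tolerances (0.01 BIC units; 10⁻⁹ on p-values
and accuracies, which are discrete at n = 20) before the documented
tie-break: smaller subset first, then lexicographic subset label.
LOOCV folds whose training set collapses to a single class are
predicted by the training majority and logged.

## The synthetic cohort generator

No patient-level series are distributed with studies of this design,
so the generator produces cohorts with the statistical structure the
analysis assumes, and is itself part of the tested surface. Each
patient's PS and PR series are independent first-order Markov chains on
the 2-hour grid with a hard regime switch at sedation stop — the
simplest mechanism that reproduces the qualitative pattern of
stabilization after sedation ends. Group defaults (frozen at design
time) encode:

* favorable patients: stable isochoric, photo-reactive pupils
  (isochoric self-transition 0.96 during sedation, 0.99 after;
  stationary isochoria ≈ 0.94);
* unfavorable patients: frequent state switching during sedation
  (isochoric self-transition 0.70, stationary isochoria ≈ 0.45) that
  stabilizes *toward pathological states* afterwards (abnormal-state
  self-transition 0.92);
* photo-reactivity separating the groups only mildly (stationary
  presence ≈ 0.92 vs ≈ 0.87 pre-sedation), so that pupil size carries
  most of the prognostic signal, as in the clinical pattern the
  indices were designed to expose.

Cohorts default to 14 favorable + 6 unfavorable patients; ICU stays are
drawn from a truncated normal with mean 17 and SD 9 days, sedation
lengths mean 9 and SD 6 days (both truncated below at one day, the
study-design minimum for sedation; sedation clipped to the stay), all
rounded to the 2-hour grid. GOSE is drawn uniformly from 5–8
(favorable) or 1–4 (unfavorable); only the dichotomy is consumed
downstream. A 5% missingness rate drops grid points outright (no
imputation), yielding ≈ 195 observations per patient, the scale such
bedside protocols produce over a two-to-three-week stay.

What the generator does **not** emulate: within-group heterogeneity of
dynamics (every patient in a group shares one transition matrix, so
between-patient spread comes only from chain noise and stay length),
cross-dependence between the size and reactivity chains, gradual
tapering of sedation, and any correlation between sedation length and
outcome. Passing tests therefore demonstrate the correctness and power
of the *machinery* under a favorable signal structure, not clinical
performance on real cohorts.

## Numerical choices and degenerate inputs

* Truncated-normal draws use the inverse-CDF so the RNG stream length
  is deterministic; cohorts are byte-reproducible given the seed.
* Zero-variance ANOVA inputs return NaN F ratios with a warning rather
  than float-noise F values; groups with fewer than two complete
  patients raise an explicit insufficient-data error.
* Zero pooled variance in the summary t-test gives t = 0 (equal means)
  or a flagged infinite t; chi-squares refuse tables with a zero
  marginal.
* Validation failures everywhere signal a dedicated condition class
  that the command-line wrapper maps to exit status 2.
* YAML/JSON config round-trips store transition matrices as explicit
  row lists (12 significant digits); row-stochasticity is re-validated
  to 10⁻⁹ on read.

## Problem sizes used by the test suite

Index oracles run on 1,000 random series; AUC is checked against the
exhaustive pairwise oracle on 100 random 20-patient cohorts; the
permutation check of the between-group effect uses 200 relabelings;
LR-test size uses 400 null draws; parameter recovery uses 100 replicate
cohorts of 14 + 6 patients — sizes chosen so the full suite documents
the distributional claims while remaining quick to run.

## Known limitations

The indices discard the identity of abnormal states (a series
alternating between two pathological states has the same occupancy as
one parked in a single pathological state); the 2-hour grid is an
assumption, configurable via `interval_hours`, since bedside practice
may be irregular; Firth prediction under separation is a principled
but not unique choice; and with n = 20 the asymptotic LR p-values are
mildly anticonservative, which is why model selection leans on BIC and
cross-validated accuracy alongside them.
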