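---
title: "Handling missing items in the CES-D scale: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Handling missing items in the CES-D scale: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cesdmi)
```

## The problem

The Center for Epidemiologic Studies Depression scale (CES-D) asks how often
each of 20 feelings occurred during the previous week, on a four-point
frequency scale scored 0–3. Sixteen items are negatively worded, four
positively worded; the positive ones are reverse-scored (`x -> 3 - x`) so
that higher always means more depressive symptomatology, and the 20 scored
items are summed to a total in 0–60. A total of 16 or more conventionally
indicates high depressive symptoms (hDS).

Self-administered questionnaires in large cohorts routinely come back with
items left blank. Dropping incomplete responders (complete-case analysis) or
filling the blanks with a single deterministic rule biases both the mean
score and the hDS prevalence, because incomplete responders are rarely a
random subset. This package implements a complete strategy for the problem:

* **bound classification** of partially observed responders;
* deterministic **single-imputation comparators** (minimum, maximum,
  person-mean);
* **multiple imputation by chained equations** with predictive mean matching
  (pmm), polytomous regression (polyreg) and logistic regression (logreg)
  methods, pooled by Rubin's rules;
* an **amputation study** benchmarking imputation accuracy under controlled
  MCAR deletion;
* a **pattern-mixture sensitivity analysis** for nonignorable (MNAR)
  missingness, driven by interpretable odds-ratio scenarios;
* a calibrated **synthetic cohort generator** providing the test bed for all
  of the above.

## Bound classification of partial responders

For a responder with missing items, every possible completion of the blanks
lies between the all-0 and the all-3 completion. The status is therefore
*determined* whenever the observed sum already reaches the cut-off (hDS under
the minimum completion) or the observed sum plus three points per missing
item still falls short (NhDS under the maximum completion); otherwise it is
*undetermined*. `classify_partial()` implements exactly this arithmetic and
the test suite verifies it against brute-force enumeration of all `4^k`
completions. `prevalence_bounds()` turns the determined/undetermined counts
into a prevalence interval: the lower bound imputes every blank to 0, the
upper bound to 3.

The derived status column added by `add_derived()` treats a responder's hDS
indicator as *observed* whenever the bound classification is decisive, and
as missing only when it is undetermined. This is a deliberate design choice:
a partially observed responder whose status is already certain contributes
that certainty to the status-level imputation model rather than being
re-imputed.

## Single-imputation comparators

`impute_min()`, `impute_max()` and `impute_person_mean()` complete the item
matrix deterministically. Person-mean fills each blank with the mean of the
subject's own observed items and keeps the fractional values unrounded, so
the completed total is exactly `observed_sum * 20 / n_observed`; rounding
direction would otherwise be an arbitrary extra convention, and unrounded
totals preserve the ordering minimum ≤ person-mean ≤ maximum exactly.
Person-mean is undefined for a subject with all 20 items missing; such
subjects must be excluded by the caller, which the comparison table does.

## The chained-equations engine

`mice_run()` iterates conditional imputation: missing cells are initialized
by uniform draws from each variable's observed values, then `n_iter` cycles
visit the targets in order of increasing missing count, re-imputing each
variable from the current completions of its predictors. The whole chain is
repeated independently `m` times.

Both regression engines perform *proper* imputation — the imputing
parameters are a draw from the asymptotic posterior at the fit, not the
point estimate — so that between-imputation variance reflects parameter
uncertainty:

* **pmm** fits a Bayesian linear regression (with a small scale-free ridge
  so rank-deficient designs degrade gracefully toward an intercept-plus-
  shrinkage fit), predicts observed rows with the fitted coefficients and
  missing rows with a posterior draw, and copies the observed value of one
  of the `donor_k` nearest-prediction donors. Distance ties are broken
  uniformly at random; with completely uninformative predictors this
  degenerates, correctly, to a uniform draw from the observed distribution.
  Donor copying confines imputed values to the observed support, so item
  and score imputations never need range clipping.
* **polyreg/logreg** fit a ridge-penalized multinomial (resp. logistic)
  model by damped Newton iteration, draw coefficients from the asymptotic
  normal at the penalized optimum, and sample each imputed category from
  the predicted probability vector. One pseudo-observation per response
  level, placed at the predictor centroid with weight 0.01, keeps levels
  absent from the observed rows estimable with a small nonzero probability;
  the ridge (default `1e-4`) bounds the fit under sparse categories or
  separation. Linear predictors are clamped at ±30 before exponentiation.
  The package's fitter is cross-checked against `nnet::multinom` in the
  test suite.

Four model structures are provided by `build_model()`: each item from the
other 19 (*parsimonious*), each item from the other 19 plus the 17-covariate
risk-factor block (*full*), the total score from the covariates by pmm
(*score level*), and the hDS indicator from the covariates by logistic
regression (*status level*).

Defaults and their reasons:

| parameter | default | rationale |
|---|---|---|
| `m` | 5 | the number of imputations used throughout the comparison tables; enough for stable point estimates and a defined between-imputation variance |
| `n_iter` | 10 | conservative relative to common chained-equation practice; the item models condition on 19 highly informative co-items and stabilize in a few cycles. Study-scale helpers pass 5 where many runs are replicated |
| `donor_k` | 5 | standard pmm donor-pool size: small enough to respect the local predictive distribution, large enough to avoid repeated single-donor copying |
| ridge | `1e-4` | inert for well-conditioned fits; decisive under separation |
| visit order | increasing missing count | variables easiest to impute are refreshed first, so heavier targets condition on maximally updated completions |

`pool_rubin()` combines the `m` completed-data estimates: pooled estimate =
mean, total variance = within (mean of complete-data variances) plus
`(1 + 1/m)` times between (sample variance of the estimates). For the
score's SD column the comparison tables report the mean of the per-dataset
SDs — a descriptive summary of the completed-data spread; the SEM column is
always the Rubin total-variance standard error.

## Nonignorable sensitivity analysis

All of the above assumes ignorable missingness. The sensitivity machinery
relaxes that with a pattern-mixture adjustment in three steps: fit the
ignorable imputation model; tilt its predictive distribution for
nonresponders; impute under the tilted model. For categorical items the
tilt multiplies the predicted probability of scored category `c` by an odds
ratio `theta_c` (category 0 is the reference) and renormalizes; for
continuous targets the prediction is shifted by `delta` before donor
matching, so imputations remain observed-support members drawn near the
shifted prediction.

Two conventions are deliberate:

* Odds ratios apply to the **scored** (post reverse-coding) categories for
  both item groups, so a scenario uniformly encodes "nonresponders were
  more likely to be symptomatic"; whether to tilt positive items on the raw
  or scored scale is otherwise ambiguous, and the scored convention keeps
  the direction of every `theta > 1` interpretable.
* The tilt is applied **inside every chained-equation cycle**, at the
  probability-sampling step, not as a one-off edit of a finished ignorable
  imputation: the scenario modifies the imputation model itself. The
  category sampler consumes exactly one uniform per imputed cell regardless
  of the tilt, so the identity scenario (`theta = (1,1,1)`, `delta = 0`)
  reproduces the ignorable run bit-for-bit under a shared seed — a property
  the test suite asserts literally.

`built_in_scenarios()` provides four increasingly severe scenarios, with
the positively worded items tilted harder in scenarios 2–4 (positive items
are easier to leave blank at high frequency categories). The synthetic
generator can create missingness whose deletion odds depend on the item's
own unobserved category through a known odds-ratio triplet; because the
tilt is expressed in exactly those odds ratios, imputing with the generating
triplet recovers the true prevalence while the ignorable model is biased
low — the acceptance suite demonstrates this inversion at n = 2,000.

## The amputation accuracy study

`run_accuracy_study()` deletes exactly `k` items from a 44.8% subject
fraction of a complete cohort (the incomplete-responder rate implied by the
reference cohort's printed totals), re-imputes by person-mean and by
item-level multiple imputation, and tabulates mean, variance, SEM and hDS
prevalence against the pre-amputation truth, averaged over replicates.

At desk scale the study runs on n = 2,000 subjects with a small number of
replicates, replication substituting for cohort size. The clearest
discriminator among the indicators is the score *variance*: person-mean
imputation adds per-subject sampling noise that grows with `k` (at `k = 10`
the completed total is twenty times the mean of only ten observed items),
while chained-equation imputation stays near the truth across `k`. The
per-`k` continuum is reported as a table; no special status is given to any
particular missing-count cut-off.

## The synthetic cohort generator

`generate_cohort()` draws a standard-normal latent trait per subject and
produces item `j` as the count of thresholds below
`loading_j * trait + N(0,1)` — a graded-response-style mechanism chosen
because a handful of parameters guarantees the unidimensional,
high-internal-consistency structure the instrument exhibits in practice.
The default loadings and thresholds were calibrated once, by simulation,
to three aggregate targets: Cronbach's alpha near 0.89 (achieved ≈ 0.895),
hDS prevalence near one quarter (≈ 0.27), and a dominant first
principal-component eigenvalue (λ₁/λ₂ ≈ 8). Item-level marginal
distributions are *inventions* constrained only by those aggregates.

The 17-column covariate block mirrors a standard list of depression risk
factors in a cohort of older women — age, marital/employment/education
status, reproductive and menopausal history, psychological history and
treatment variables, alcohol, smoking, sleep, hospitalizations, and a
chronic-disease count — with mild associations to the same latent trait.
Names are chosen for readability; the distributions are documented
inventions, not estimates of any real cohort's marginals.

What passing tests on this generator do **not** show about real data: real
item non-response clusters within questionnaire pages, real covariates are
themselves incomplete, real populations mix subgroups with different item
functioning, and a real MNAR mechanism need not follow the logistic
own-category form the generator uses. The generator supports the
*machinery* claims (unbiasedness under MCAR/MAR, correct inversion of a
known MNAR tilt), not claims about any particular cohort.

## Numerical choices and degenerate inputs

* Percentages in reports are rounded half-away-from-zero to one decimal
  (base `round()` would round half-to-even).
* pmm donor distances are compared with a relative tolerance of `1e-7`;
  donors tied with the k-th nearest get an equal selection chance, and a
  massive tie set (constant predictions) degenerates to a uniform draw over
  it.
* A variable with no observed values cannot be imputed and errors
  immediately, as does `m < 2`, a self-predicting variable, a missing-data
  variable with method `"none"`, thresholds that are not strictly
  increasing, and person-mean on an all-missing row.
* Seeds: every stochastic entry point takes an explicit seed, restores the
  caller's RNG state, and is bit-reproducible; the `m` chains consume one
  sequential stream.

## Problem sizes

The shipped test and acceptance workloads use n = 2,000 cohorts for the
recovery and sensitivity studies (m = 5, 5 chained cycles, 2–3 replicates),
n = 5,000 for generator calibration checks, and n ≤ 1,500 elsewhere; these
sizes give Monte-Carlo standard errors around one prevalence point, which
is the resolution at which the package's qualitative claims are stated.

## Known limitations

* Convergence diagnostics are limited to the per-iteration trace of imputed
  means/SDs; no R-hat-style statistic is computed.
* The status-level MNAR path accepts a single odds ratio but ships no
  calibrated default scenarios.
* Passive and multilevel imputation are out of scope, as are selection-model
  MNAR approaches.
* The covariate generator draws each covariate conditionally on the trait
  alone; covariate–covariate partial associations beyond the trait are not
  modeled.
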