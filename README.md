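# cesdmi — missing-data strategies for the CES-D depression scale

The CES-D is a 20-item self-report scale for depressive symptoms: each item
is scored 0–3 (four positively worded items reverse-scored), the items are
summed to a total in 0–60, and a total ≥ 16 flags *high depressive
symptoms* (hDS). In large cohort questionnaires a substantial fraction of
responders leave items blank, and how those blanks are handled changes the
estimated prevalence of hDS by several percentage points.

`cesdmi` is aimed at epidemiologists and biostatisticians analysing CES-D
(or similar summed ordinal scales) with missing items. It provides, as one
tested pipeline:

* **Scoring and bound classification** — a partially observed responder is
  classified hDS if their observed sum already reaches 16, NhDS if
  `observed_sum + 3·k < 16` with `k` items missing, and *undetermined*
  otherwise; determined/undetermined counts yield prevalence bounds
  `[n_hDS, n_hDS + n_undet] / N` (the all-0 and all-3 completions).
* **Single-imputation comparators** — minimum (blank → 0), maximum
  (blank → 3), and person-mean (blank → mean of the subject's observed
  items, total `= observed_sum · 20 / n_observed`).
* **Multiple imputation by chained equations** — predictive mean matching,
  ridge-penalized polytomous and logistic regression with posterior-style
  parameter draws; item-level (parsimonious / full), score-level and
  status-level model structures; Rubin's rules pooling
  (`T = W + (1 + 1/m)·B`).
* **MCAR amputation study** — delete exactly `k` items from a 44.8%
  subject fraction of a complete cohort and benchmark each method's mean,
  variance, SEM and prevalence against the pre-amputation truth.
* **Pattern-mixture MNAR sensitivity analysis** — tilt the imputation
  model's category probabilities for nonresponders by odds ratios
  `p'_c ∝ p_c·θ_c` (or shift continuous predictions by δ before donor
  matching) and re-impute under four increasingly severe built-in
  scenarios.
* **Psychometrics and a calibrated synthetic cohort generator** —
  Cronbach's alpha, PCA eigenvalue spectrum, and a graded-response-style
  generator (unidimensional latent trait, 17 risk-factor covariates,
  configurable MCAR/MAR/MNAR missingness) used as the test bed.

## Worked example

```r
library(cesdmi)

cohort <- generate_cohort(2000, seed = 1)          # complete synthetic cohort
truth  <- score_total(cohort)
mean(truth); 100 * mean(truth >= 16)
#> complete-data mean 11.29, hDS prevalence 27.9%

gm <- generate_missingness(cohort, missingness_spec("MAR"), seed = 2)
sum(rowSums(gm$mask) > 0)
#> 903 of 2000 subjects now have missing items

prevalence_bounds_from_items(gm$cohort)
#> hDS prevalence between 22.8% and 50.8% (N = 2000)

spec <- build_model("items_parsimonious", method = "pmm", m = 5)
sets <- mice_run(gm$cohort, spec, seed = 3)
pooled_summary(sets)
#>      n  mean    sd    sem pct_hds pct_hds_se
#> 1 2000 11.32 10.47 0.2353   27.76      1.014
```

Reading the output: with 45% of subjects incomplete, the deterministic
bounds only bracket the prevalence between 22.8% and 50.8%, while
item-level multiple imputation recovers the complete-data values (mean
11.32 vs 11.29; prevalence 27.8% vs 27.9%) with an honest standard error
that includes between-imputation variance.

For the nonignorable sensitivity analysis, pass a scenario to the same
engine:

```r
sensitivity_run(gm$cohort,
                build_model("items_parsimonious", method = "polyreg", m = 5),
                seed = 3)      # identity + the four built-in odds-ratio scenarios
```

A thin command-line wrapper over these functions is installed at
`system.file("cli/cesd-pipeline.R", package = "cesdmi")`, with subcommands
`generate`, `ampute`, `table1`, `table3`, `sensitivity`, `accuracy` and
`psychometrics`.

See `vignettes/handling-missing-cesd.Rmd` for the full account of the
models, parameter defaults and design choices.

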