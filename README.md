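# ostai

Derivation, application and evaluation of simple integer risk indices
that triage postmenopausal women for bone mineral density (BMD) testing
by DXA.

Osteoporosis is diagnosed when the BMD T-score at the lumbar spine,
femoral neck or total hip is ≤ −2.5 SD, but population-wide DXA is
impractical, so clinics pre-screen with indices built from variables any
visit collects. The OSTAi index is

    OSTAi = round( 0.2 × (weight [kg] − age [years]) )

with DXA referral for values strictly below −1, and risk categories
low (≥ −1), medium (−2, −3) and high (≤ −4). The package provides:

* **Scoring** — `ostai_score()`, `ostai_decision()`, and the NOF 2013
  rule-based comparator `classify_nof2013()` (refer women 65+, or younger
  women with BMI < 18.5, prior fracture, glucocorticoid use, rheumatoid
  arthritis or secondary osteoporosis).
* **Cohort handling** — schema-checked CSV I/O (`read_cohort()`), the
  study exclusion cascade with an auditable QC log
  (`apply_exclusions()`), the WHO case definition
  (`classify_osteoporosis()`), and site-combination bookkeeping
  (`tabulate_site_combinations()`, `site_totals()`).
* **Index derivation** — the full pipeline `derive_index()`: univariate
  screen at p < 0.05, multivariable OLS of the lowest T-score on the
  retained factors (per-10-unit increments), integer index weights by the
  points-system method (`make_index_weights()`), backward item reduction
  under an AUC-retention tolerance (`item_reduction()`), and
  Youden-optimal integer cutoff selection (`select_cutoff()`).
* **Evaluation** — `diagnostic_report()` (2×2 counts, sensitivity /
  specificity / PPV / NPV as exact count fractions, ROC with DeLong or
  Hanley–McNeil CI, prevalence by risk category), `compare_rules()`
  (paired DeLong test), plus `autoplot()` / `plot_*()` figures and
  broom-style `tidy()` / `glance()` methods throughout.
* **Synthetic cohorts** — `generate_cohort()` draws seeded,
  ground-truthed cohorts matching the published development cohort's
  marginals, questionnaire missingness, T-score coefficients and 41.3%
  osteoporosis prevalence, so every stage is testable without the
  (undistributed) participant-level study data; `inject_pathologies()`
  builds QC fixtures.

A thin command-line front end with subcommands
`simulate | score | derive | evaluate | compare | reproduce` lives at
`inst/cli/ostai.R`.

## A worked example

```r
library(ostai)

cohort <- generate_cohort(12175, seed = 42) |>
  apply_exclusions() |>
  classify_osteoporosis()

model <- derive_index(cohort)
model
#> <index_model> 2 variables, anchor age_5yr (0.183)
#>  variable weight increment referent       beta          se             p
#>       age     -2        10       50 -0.3656378 0.009434905 1.036551e-309
#>    weight      2        10       50  0.3717342 0.010212382 2.571438e-275
#> screening cutoff: score < -1 is positive
```

The derivation lands on the published tool: age and weight with weights
−2 and +2 per 10 units — i.e. exactly `0.2 × (weight − age)` — at the
published cutoff −1.

```r
ostai <- diagnostic_report(cohort, "ostai", cutoff = -1)
nof   <- diagnostic_report(cohort, "nof2013")
ostai
#> <diagnostic_report> rule ostai on 12038 women (prevalence 40.9%)
#>   tp 3584  fp 2979  fn 1342  tn 4133;  referral 54.5%
#>   sensitivity 72.8% (3584/4926)
#>   specificity 58.1% (4133/7112)
#>   ppv 54.6% (3584/6563)
#>   npv 75.5% (4133/5475)
#>   AUC 0.712 (0.703-0.721, delong)
compare_rules(ostai, nof)$auc_diff
#> [1] 0.1111573
```

Sensitivity/specificity, predictive values, referral burden and the
OSTAi-vs-NOF AUC advantage all sit close to the published development
values (73.1%/62.0%, PPV 57.5%, NPV 76.6%, AUC difference 0.121);
exact digit-for-digit table reproduction needs the real cohort, which is
why the published summary counts are bundled as verification fixtures in
`ostai_reference()` and replayed by `reproduce_tables(fixtures = TRUE)`.

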