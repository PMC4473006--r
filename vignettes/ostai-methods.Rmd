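---
title: "Deriving and evaluating the OSTAi osteoporosis screening index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating the OSTAi osteoporosis screening index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ostai)
library(dplyr)
```

## The problem

Dual-energy X-ray absorptiometry (DXA) is the diagnostic standard for
osteoporosis — a T-score of −2.5 SD or below at the lumbar spine, femoral
neck or total hip — but scanning every postmenopausal woman is not
practical. Simple pre-screening indices triage women toward DXA referral.
The OSTA family of indices does this with two numbers every clinic has:

$$\mathrm{OSTAi} = \operatorname{round}\bigl(0.2\,(\text{weight
[kg]} - \text{age [years]})\bigr),$$

with referral ("screen positive") for index values strictly below −1, and
risk categories low (≥ −1), medium (−2, −3) and high (≤ −4). This package
implements that score, the NOF 2013 rule-based comparator (refer all women
65+, or younger women with low BMI, prior fracture, glucocorticoid use, or
a bone-loss condition), the complete pipeline that derives such an index
from a cohort, and the diagnostic-performance machinery used to judge it.

## The derivation pipeline

The index is rebuilt from participant-level data in four stages, mirroring
the way such tools are developed:

1. **Univariate screen** (`univariate_screen()`). Each candidate risk
   factor from the FRAX list is regressed alone against the response
   T-score; candidates with p < α (default 0.05) are retained. Continuous
   variables enter per 10 units so coefficients are comparable increments;
   binary questionnaire items enter yes = 1 / no = 0, with unanswered
   items excluded from that candidate's complete cases — an unanswered
   question is never coerced to "no".

2. **Multivariable fit** (`fit_multivariable()`). Ordinary least squares
   of the response on all retained variables, complete-case over that
   variable set. The response throughout is the *lowest* T-score across
   the three sites: the case definition operates on the lowest T-score,
   so the regressions target the same scale the screen is judged on.

3. **Integer weighting** (`make_index_weights()`). Coefficients become
   signed integer weights by dividing by a scale anchor and rounding
   (halves away from zero). The default anchor follows the points-system
   convention of Framingham-style risk scores: one point is the T-score
   change associated with five years of age, i.e. half the per-decade age
   coefficient. Anchoring on the most precisely estimated coefficient
   keeps the weight scale stable under resampling, whereas anchoring on
   the *smallest* coefficient (available as `anchor = "min_beta"`) is
   noisy: the minimum of several estimated coefficients is biased
   downward, and in repeated samples it inflates every weight by one unit
   in a substantial fraction of draws. Both anchors reproduce the
   published OSTAi development weights (−2, 1, 2, 1, −1, −2, −1) from the
   published coefficients.

4. **Item reduction and cutoff** (`item_reduction()`,
   `select_cutoff()`). Backward elimination drops, at each step, the
   variable whose removal least decreases the AUC for osteoporosis,
   refitting the regression and recomputing weights after each drop,
   while the reduced model stays within `tol_auc` (default 0.01) of the
   full model's AUC. All eliminations are judged on a fixed evaluation
   set — the rows the full model can score — so candidate models are
   compared paired on identical participants; comparing each model on its
   own scoreable rows instead would confound model quality with sample
   composition and roughly doubles the variance of the stopping decision.
   The default tolerance mirrors the discrimination loss the published
   development accepted when it reduced seven variables to age and
   weight. Finally every integer cutoff in the observed score range is
   evaluated with positivity `score < cutoff`, and the cutoff maximising
   Youden's J is chosen, ties broken toward the higher-sensitivity
   cutoff.

A two-variable age/weight model with weights (−2, +2), increments of 10
and referents of 50 scores *identically* to the published OSTAi formula —
the derivation output plugs straight into the scoring engine, and the test
suite asserts this equivalence.

## Diagnostic evaluation

`diagnostic_report()` evaluates a rule against the WHO case definition:
the 2×2 confusion matrix; sensitivity, specificity, PPV and NPV reported
both as proportions and exact count fractions (so published tables can be
reproduced digit-for-digit at one-decimal rounding); the ROC curve; and
prevalence by risk category. Orientation is always "lower score = more at
risk", with thresholds swept as `score < t`.

The AUC is computed by the trapezoidal rule over thresholds at every
observed score value, which is algebraically identical to the
Mann–Whitney concordance probability with ties counted one half (the test
suite verifies this against an O(n²) pairwise oracle to 10⁻¹²).
Confidence intervals use the DeLong variance estimator computed from
midrank placement values; the Hanley–McNeil approximation is available as
a cross-check. `compare_rules()` tests the AUC difference of two rules
with the paired DeLong estimator, using the per-participant scores each
report retains. For a binary rule such as NOF 2013 the ROC is the
two-segment curve through its single operating point, so its AUC is
exactly (sensitivity + specificity)/2; published AUCs for binary rules
that do not satisfy this identity cannot be reproduced from counts and
are not treated as targets.

## The synthetic cohort generator

`generate_cohort()` emulates the published development cohort so that
every pipeline stage is testable with known ground truth:

* **Demographics.** Age, height, weight and menopause age are drawn from
  a correlated multivariate normal with the published means and SDs
  (66.0 ± 9.6 y, 153.9 ± 5.8 cm, 56.9 ± 8.8 kg, 49.3 ± 4.5 y), truncated
  at ±4 SD. The correlations (age–height −0.30, age–weight −0.15,
  height–weight +0.40, age–menopause +0.10) are generator assumptions —
  the development study reports only marginals. A menopause age drawn
  above the woman's current age (about 5% of rows) is recorded at her
  current age; rejecting such rows instead would bias the age marginal
  upward by almost a year.

* **Risk factors.** Bernoulli draws at the published prevalences
  (e.g. prior fracture 15.0%, smoking 1.3%), then masked to missing
  independently per question at the published questionnaire response
  rates (63–72%), i.e. missing completely at random.

* **T-scores.** Each site's T-score is a linear function of the
  covariates — per-10-unit coefficients default to the published
  multivariable model, with the four screened-out factors at zero — plus
  a shared noise component (SD 0.75, giving inter-site correlations of
  about 0.6–0.7, typical of DXA data) and a site-specific residual sized
  so the *total* per-site SDs match the published 1.3 / 1.1 / 1.1.
  Site intercepts are then shifted by a single calibration constant,
  found by quantile inversion on a 200,000-row calibration sample, so the
  prevalence of a lowest T-score ≤ −2.5 hits the 41.3% target; on fresh
  draws of 100,000 the realised prevalence lands within ±0.5%.

The generator pins the Mersenne–Twister/Inversion RNG explicitly, so a
seed reproduces a cohort byte-identically across platforms, and it
returns the generating coefficients and per-participant latent signal as
ground truth for parameter-recovery tests.

**What the generator does not emulate.** Joint structure beyond the
configured moments: no site or geographic clustering, no informative
non-response, no age-dependence of risk-factor prevalence, and a purely
linear covariate→T-score map with Gaussian noise. Passing tests on
synthetic cohorts therefore demonstrate that the *algorithms* behave as
specified under the published study conditions, not that the real cohort's
raw data would reproduce — the participant-level study data are not
distributed, and the published real-data AUCs (0.739 / 0.618) are not
reproduction targets.

## Numerical choices and edge cases

* Rounding of index values is *nearest, halves away from zero* (−1.5 →
  −2), the natural reading of "round off"; truncation toward zero, as in
  the original OSTA, is an option (`rounding = "truncate"`).
* A decision at the cutoff is negative (strict `<`), consistent with the
  published low-risk boundary "≥ −1" and sensitivity definition.
* Extreme-value QC uses strict `>` (exactly k·SD is retained), with
  means/SDs computed once, per variable on complete cases, on the sample
  surviving the categorical exclusions; the recorded reference statistics
  make the operation idempotent and auditable.
* A metric with a zero denominator is reported as undefined (`NA`), never
  as zero. A degenerate cohort (single class) is a domain error for
  cutoff selection and ROC analysis. A nearly flat Youden profile
  (J < 0.05 everywhere) still returns a cutoff but warns.
* Integer weights are never zero: a coefficient below half the anchor
  receives the minimal weight ±1, so a retained variable always
  contributes with the sign of its effect.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at the sizes a laptop handles
comfortably while still matching the study's scale where it matters:
marginal checks at n = 50,000, prevalence calibration at n = 100,000,
parameter recovery and endpoint-recovery of the derivation at n = 20,000
over 20 seeds, and the permutation cross-check of the paired DeLong test
with 10,000 shuffles at n = 400.

## Known limitations

* The backward-elimination stopping rule compares against the full-model
  AUC with a fixed tolerance; when a cohort's true incremental AUC of the
  dropped block sits near the tolerance, the stopping point is
  sample-dependent. This is a property of the procedure, not of the
  implementation — the published development itself accepted a loss
  (0.749 → 0.739) exactly at the default tolerance.
* The NOF 2013 mapping uses the questionnaire fields actually collected:
  "high-risk medication" → glucocorticoids; "disease or condition
  associated with bone loss" → rheumatoid arthritis or secondary
  osteoporosis. Smoking and alcohol are FRAX factors but not referral
  triggers under this rule.
* Fracture outcomes are out of scope: the index discriminates prevalent
  osteoporosis, not incident fracture.

## A worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(12175, seed = 42) |>
  apply_exclusions() |>
  classify_osteoporosis()

model <- derive_index(cohort)
tidy(model)

ostai <- diagnostic_report(cohort, "ostai", cutoff = -1)
nof <- diagnostic_report(cohort, "nof2013")
compare_rules(ostai, nof)

autoplot(ostai$roc)
plot_index_vs_tscore(cohort)
```
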