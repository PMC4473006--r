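Package: ostai
Title: Osteoporosis Screening Indices for Postmenopausal Women
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deriving, applying and evaluating simple integer risk
    indices that triage postmenopausal women for bone mineral density (BMD)
    testing. Implements the OSTAi index (0.2 * (weight in kg - age in years),
    rounded to an integer) with its low/medium/high risk categories, the
    NOF 2013 rule-based referral comparator, the full cohort-to-index
    derivation pipeline (univariate screen, multivariable regression,
    integer index weights by the points-system method, backward item
    reduction under an AUC-retention tolerance, and Youden-optimal cutoff
    selection), and a diagnostic-performance engine (confusion matrices,
    sensitivity/specificity/PPV/NPV, ROC curves with DeLong confidence
    intervals, risk-category prevalence, and paired head-to-head rule
    comparison). A seeded synthetic-cohort generator emulates the marginal
    distributions, questionnaire missingness and T-score structure of the
    published OSTAi development cohort so every pipeline stage is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
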