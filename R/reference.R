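#' Published reference values of the OSTAi development study
#'
#' Summary numbers printed in the original OSTAi development study
#' (a nationwide DXA survey of 12,175 Taiwanese postmenopausal women),
#' bundled as verification fixtures: the raw participant-level data are not
#' distributed, but every table-level quantity the package computes can be
#' checked against these counts and coefficients.
#'
#' @return A list with elements
#' \describe{
#'   \item{cohort}{named vector: total `n`, `n_osteoporotic`,
#'     `n_non_osteoporotic`.}
#'   \item{site_combinations}{tibble in the [tabulate_site_combinations()]
#'     layout: osteoporotic women by exact site subset.}
#'   \item{multivariable}{tibble of the seven retained variables with their
#'     multivariable coefficients (per 10 units for continuous variables,
#'     yes-vs-no for binaries), standard errors and published integer index
#'     weights.}
#'   \item{univariate_dropped}{tibble of the four candidates dropped by the
#'     univariate screen with their univariate p-values.}
#'   \item{confusion}{tibble of the published 2x2 counts for the OSTAi
#'     index at cutoff -1 and for the NOF 2013 rule.}
#'   \item{categories}{tibble of osteoporotic cases and totals per OSTAi
#'     risk category.}
#'   \item{auc}{named vector of published AUCs (seven-variable model,
#'     two-variable model / OSTAi, NOF 2013).}
#' }
#' @export
ostai_reference <- function() {
  list(
    cohort = c(n = 12175, n_osteoporotic = 5027, n_non_osteoporotic = 7148),
    site_combinations = tibble(
      combination = c(
        "lumbar_spine_only", "femoral_neck_only", "total_hip_only",
        "lumbar_spine+femoral_neck", "lumbar_spine+total_hip",
        "femoral_neck+total_hip", "lumbar_spine+femoral_neck+total_hip"
      ),
      n = c(1896, 850, 16, 1209, 31, 176, 849)
    ),
    multivariable = tibble(
      variable = c("age", "height", "weight", "menopause_age",
                   "previous_fracture", "current_smoking", "glucocorticoids"),
      beta = c(-0.364, 0.175, 0.343, 0.161, -0.228, -0.293, -0.198),
      se = c(0.011, 0.019, 0.012, 0.022, 0.028, 0.090, 0.039),
      index_weight = c(-2, 1, 2, 1, -1, -2, -1)
    ),
    univariate_dropped = tibble(
      variable = c("parent_hip_fracture", "rheumatoid_arthritis",
                   "secondary_osteoporosis", "alcohol_3plus_units"),
      p = c(0.634, 0.552, 0.124, 0.987)
    ),
    confusion = tibble(
      rule = c("ostai", "nof2013"),
      tp = c(3674, 3936), fp = c(2719, 3813),
      fn = c(1353, 1091), tn = c(4429, 3335)
    ),
    categories = tibble(
      category = c("low", "medium", "high"),
      cases = c(1353, 1418, 2256),
      total = c(5782, 3170, 3223)
    ),
    auc = c(seven_variable = 0.749, ostai = 0.739, nof2013 = 0.618)
  )
}
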