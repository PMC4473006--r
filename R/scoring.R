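#' Compute the OSTAi score
#'
#' The OSTAi index for a postmenopausal woman is
#' `0.2 * (weight in kg - age in years)`, rounded to an integer. Risk
#' categories follow the published cutpoints: `low` for values >= -1,
#' `high` for values <= -4, and `medium` in between (integer values -2 and
#' -3). Rounding is to the nearest integer with halves away from zero by
#' default; `"truncate"` (toward zero, as in the original OSTA) is
#' available as an option.
#'
#' @param data tibble with columns `age` (years) and `weight` (kg).
#' @param rounding `"nearest"` (default) or `"truncate"`.
#' @return `data` with columns `ostai_raw`, `ostai_value` (integer) and
#'   `ostai_category` (factor `low` < `medium` < `high`) appended. Rows with
#'   a missing age or weight get `NA` scores.
#' @examples
#' ostai_score(tibble::tibble(age = c(50, 70, 66), weight = c(50, 45, 56.9)))
#' @export
ostai_score <- function(data, rounding = c("nearest", "truncate")) {
  rounding <- match.arg(rounding)
  if (!all(c("age", "weight") %in% names(data))) {
    stop_ostai("ostai_score needs columns age and weight", "ostai_domain_error")
  }
  bad <- (!is.na(data$age) & data$age <= 0) | (!is.na(data$weight) & data$weight <= 0)
  if (any(bad)) {
    stop_ostai("age and weight must be positive", "ostai_domain_error")
  }
  raw <- 0.2 * (data$weight - data$age)
  value <- apply_rounding(raw, rounding)
  data$ostai_raw <- raw
  data$ostai_value <- as.integer(value)
  data$ostai_category <- ostai_category(value)
  data
}

#' Risk category of an integer OSTAi value
#'
#' @param value integer score values.
#' @return ordered factor `low` < `medium` < `high`; the three categories
#'   partition the integers (`low`: >= -1, `medium`: -3..-2, `high`: <= -4).
#' @export
ostai_category <- function(value) {
  cat <- ifelse(value >= -1, "low", ifelse(value <= -4, "high", "medium"))
  factor(cat, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Screening decision from the OSTAi score
#'
#' A woman screens positive (referred for BMD measurement) when her integer
#' index value lies strictly below the cutoff; a value at the cutoff is
#' negative, matching the published low-risk boundary (values >= -1 are
#' low risk at the default cutoff of -1).
#'
#' @param data tibble containing `ostai_value` (computed with
#'   [ostai_score()] if absent and `age`/`weight` are available).
#' @param cutoff integer cutoff (default -1).
#' @param rounding passed to [ostai_score()] when scores must be computed.
#' @return `data` with a logical column `ostai_positive` appended.
#' @export
ostai_decision <- function(data, cutoff = -1, rounding = "nearest") {
  if (cutoff != round(cutoff)) {
    stop_ostai("cutoff must be an integer", "ostai_domain_error")
  }
  if (!"ostai_value" %in% names(data)) data <- ostai_score(data, rounding)
  data$ostai_positive <- data$ostai_value < cutoff
  data
}

#' NOF 2013 referral rule
#'
#' Classifies each woman under the National Osteoporosis Foundation 2013
#' recommendation for BMD testing: positive if aged 65 or older, or younger
#' than 65 with at least one qualifying clinical risk factor -- low body
#' weight (BMI < 18.5 kg/m^2), prior fragility fracture, high-risk
#' medication use (glucocorticoids), or a disease or condition associated
#' with bone loss (rheumatoid arthritis or secondary osteoporosis). An
#' unanswered questionnaire item never fires a criterion. When height or
#' weight is missing for a woman under 65, the BMI criterion is recorded as
#' not evaluable and the remaining criteria are still checked.
#'
#' @param data cohort tibble with `age`, `height`, `weight` and the risk
#'   factor columns.
#' @return `data` with columns `nof2013_positive` (logical),
#'   `nof2013_triggers` (comma-separated criterion codes, `""` when none)
#'   and `nof2013_bmi_evaluable` (logical) appended.
#' @export
classify_nof2013 <- function(data) {
  if (!"age" %in% names(data) || any(is.na(data$age))) {
    stop_ostai("age is required for every participant", "ostai_domain_error")
  }
  n <- nrow(data)
  bmi <- data$weight / (data$height / 100)^2
  bmi_eval <- !is.na(bmi)
  get01 <- function(col) {
    if (col %in% names(data)) data[[col]] %in% 1L else rep(FALSE, n)
  }
  criteria <- list(
    age_ge_65 = data$age >= 65,
    low_bmi = data$age < 65 & bmi_eval & bmi < 18.5,
    previous_fracture = data$age < 65 & get01("previous_fracture"),
    glucocorticoids = data$age < 65 & get01("glucocorticoids"),
    rheumatoid_arthritis = data$age < 65 & get01("rheumatoid_arthritis"),
    secondary_osteoporosis = data$age < 65 & get01("secondary_osteoporosis")
  )
  fired <- do.call(cbind, criteria)
  data$nof2013_positive <- rowSums(fired) > 0
  data$nof2013_triggers <- apply(fired, 1, function(row) {
    paste(names(criteria)[row], collapse = ",")
  })
  data$nof2013_bmi_evaluable <- ifelse(data$age >= 65, NA, bmi_eval)
  data
}
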