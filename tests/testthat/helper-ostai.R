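# Shared fixtures and independent oracles, built in code at test time.

# One schema-complete participant row with sensible defaults; override any
# field by name.
participant <- function(id = "P1", sex = "female", menopausal = "post",
                        age = 66, height = 154, weight = 57,
                        menopause_age = 49,
                        t_lumbar = -1.5, t_femoral_neck = -1.5,
                        t_total_hip = -1.0,
                        previous_fracture = 0L, parent_hip_fracture = 0L,
                        current_smoking = 0L, glucocorticoids = 0L,
                        rheumatoid_arthritis = 0L, secondary_osteoporosis = 0L,
                        alcohol_3plus_units = 0L) {
  tibble::tibble(
    id = id, sex = sex, menopausal = menopausal, age = age, height = height,
    weight = weight, menopause_age = menopause_age, t_lumbar = t_lumbar,
    t_femoral_neck = t_femoral_neck, t_total_hip = t_total_hip,
    previous_fracture = previous_fracture,
    parent_hip_fracture = parent_hip_fracture,
    current_smoking = current_smoking, glucocorticoids = glucocorticoids,
    rheumatoid_arthritis = rheumatoid_arthritis,
    secondary_osteoporosis = secondary_osteoporosis,
    alcohol_3plus_units = alcohol_3plus_units
  )
}

cohort_of <- function(...) dplyr::bind_rows(...)

# O(n^2) pairwise concordance: P(case scores below control), ties one half.
pairwise_auc <- function(score, truth) {
  cases <- score[truth]
  controls <- score[!truth]
  total <- 0
  for (x in cases) {
    total <- total + sum(x < controls) + 0.5 * sum(x == controls)
  }
  total / (length(cases) * length(controls))
}

# Independent row-by-row reimplementation of the exclusion cascade.
brute_force_filter <- function(data, sd_multiple = 3) {
  keep <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(data))) {
    r <- data[i, ]
    if (is.na(r$sex) || r$sex != "female") keep[i] <- FALSE
    else if (is.na(r$menopausal) || r$menopausal != "post") keep[i] <- FALSE
    else if (is.na(r$t_lumbar) || is.na(r$t_femoral_neck) ||
             is.na(r$t_total_hip)) keep[i] <- FALSE
  }
  base <- data[keep, ]
  for (v in c("age", "height", "weight", "menopause_age")) {
    mu <- mean(base[[v]], na.rm = TRUE)
    s <- stats::sd(base[[v]], na.rm = TRUE)
    for (i in seq_len(nrow(data))) {
      if (!keep[i]) next
      x <- data[[v]][i]
      if (!is.na(x) && abs(x - mu) > sd_multiple * s) keep[i] <- FALSE
    }
  }
  data[keep, ]
}

# Published development-model coefficients (per 10 units / yes-vs-no) and
# their integer index weights.
published_betas <- function() {
  tibble::tibble(
    variable = c("age", "height", "weight", "menopause_age",
                 "previous_fracture", "current_smoking", "glucocorticoids"),
    beta = c(-0.364, 0.175, 0.343, 0.161, -0.228, -0.293, -0.198)
  )
}
published_weights <- c(-2L, 1L, 2L, 1L, -1L, -2L, -1L)
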