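#' Round half away from zero
#'
#' Commercial rounding: halves move away from zero, so -1.5 becomes -2 and
#' 1.5 becomes 2. This is the convention used when integer index values are
#' formed from raw scores; R's own `round()` rounds halves to even and is
#' not suitable for reproducing published integer indices.
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @examples
#' round_half_away(c(-1.5, -0.5, 0.5, 1.5, -1.82))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Truncate toward zero
#'
#' @param x numeric vector.
#' @return numeric vector of integers (as doubles).
#' @keywords internal
trunc_toward_zero <- function(x) trunc(x)

# Apply the selected rounding mode to a raw score.
apply_rounding <- function(x, rounding = c("nearest", "truncate")) {
  rounding <- match.arg(rounding)
  if (rounding == "nearest") round_half_away(x) else trunc_toward_zero(x)
}

# Continuous cohort variables and their per-unit scale used throughout the
# derivation machinery (regressions use per-10-unit increments).
.cont_vars <- c("age", "height", "weight", "menopause_age")

.binary_vars <- c(
  "previous_fracture", "parent_hip_fracture", "current_smoking",
  "glucocorticoids", "rheumatoid_arthritis", "secondary_osteoporosis",
  "alcohol_3plus_units"
)

.t_score_cols <- c("t_lumbar", "t_femoral_neck", "t_total_hip")

.site_names <- c("lumbar_spine", "femoral_neck", "total_hip")

# Map a cohort column to the design-matrix scale: continuous variables enter
# per 10 units, binaries as 0/1.
scale_covariate <- function(data, variable) {
  x <- data[[variable]]
  if (variable %in% .cont_vars) x / 10 else as.numeric(x)
}

# Default referent values on the natural scale (age 50 years, weight 50 kg
# and so on); binaries are referenced at "no". Referents shift an index
# score by a constant and never affect discrimination.
default_referents <- function(variables) {
  ref <- c(age = 50, height = 150, weight = 50, menopause_age = 50)
  out <- setNames(numeric(length(variables)), variables)
  hit <- intersect(variables, names(ref))
  out[hit] <- ref[hit]
  out
}

default_increments <- function(variables) {
  setNames(ifelse(variables %in% .cont_vars, 10, 1), variables)
}

fmt_pct <- function(x, digits = 1) round(100 * x, digits)

stop_ostai <- function(message, class, ...) {
  abort(message, class = c(class, "ostai_error"), ...)
}
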