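#' Configuration of the synthetic-cohort generator
#'
#' Bundles every distributional assumption of the generator. Defaults
#' emulate the published OSTAi development cohort of Taiwanese
#' postmenopausal women: marginal means/SDs of the four continuous
#' demographics, per-question risk-factor prevalences and questionnaire
#' response rates, T-score regression coefficients on the per-10-unit /
#' yes-vs-no scale, total per-site T-score SDs, and an overall osteoporosis
#' prevalence target of 41.3% to which site intercepts are calibrated. The
#' continuous-variable correlations and the shared/site split of the
#' T-score noise are generator assumptions (chosen to give realistic
#' inter-site T-score correlations of about 0.6-0.7), not published
#' quantities.
#'
#' @param n_cal size of the internal calibration sample used to set the
#'   intercept shift that hits `target_prevalence`.
#' @param ... named overrides of any default listed below.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(..., n_cal = 200000) {
  cfg <- list(
    means = c(age = 66.0, height = 153.9, weight = 56.9, menopause_age = 49.3),
    sds = c(age = 9.6, height = 5.8, weight = 8.8, menopause_age = 4.5),
    corr = matrix(
      c(1, -0.30, -0.15, 0.10,
        -0.30, 1, 0.40, 0,
        -0.15, 0.40, 1, 0,
        0.10, 0, 0, 1),
      4, 4, dimnames = list(.cont_vars, .cont_vars)
    ),
    prevalences = c(
      previous_fracture = 0.150, parent_hip_fracture = 0.107,
      current_smoking = 0.013, glucocorticoids = 0.068,
      rheumatoid_arthritis = 0.074, secondary_osteoporosis = 0.084,
      alcohol_3plus_units = 0.007
    ),
    response_rates = c(
      previous_fracture = 8624, parent_hip_fracture = 7826,
      current_smoking = 8730, glucocorticoids = 8507,
      rheumatoid_arthritis = 8494, secondary_osteoporosis = 8617,
      alcohol_3plus_units = 8671
    ) / 12175,
    coefs = c(
      age = -0.364, height = 0.175, weight = 0.343, menopause_age = 0.161,
      previous_fracture = -0.228, parent_hip_fracture = 0,
      current_smoking = -0.293, glucocorticoids = -0.198,
      rheumatoid_arthritis = 0, secondary_osteoporosis = 0,
      alcohol_3plus_units = 0
    ),
    site_means = c(lumbar = -1.8, femoral_neck = -1.8, total_hip = -1.0),
    site_sds = c(lumbar = 1.3, femoral_neck = 1.1, total_hip = 1.1),
    shared_noise_sd = 0.75,
    target_prevalence = 0.413,
    trunc_sd = 4,
    n_cal = n_cal
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop_ostai(paste0("unknown generator settings: ",
                      paste(unknown, collapse = ", ")), "ostai_domain_error")
  }
  cfg <- modifyList(cfg, overrides)
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  ev <- eigen(cfg$corr, symmetric = TRUE, only.values = TRUE)$values
  if (!isTRUE(all.equal(cfg$corr, t(cfg$corr))) || any(ev <= 0)) {
    stop_ostai("correlation matrix must be symmetric positive-definite",
               "ostai_domain_error")
  }
  if (any(cfg$prevalences < 0 | cfg$prevalences > 1) ||
      any(cfg$response_rates < 0 | cfg$response_rates > 1)) {
    stop_ostai("prevalences and response rates must lie in [0, 1]",
               "ostai_domain_error")
  }
  if (any(cfg$sds <= 0) || any(cfg$site_sds <= 0) || cfg$shared_noise_sd < 0) {
    stop_ostai("scale parameters must be positive", "ostai_domain_error")
  }
  # per-site residual variance must be achievable given the linear signal
  if (any(cfg$site_sds^2 - eta_variance(cfg) - cfg$shared_noise_sd^2 <= 0)) {
    stop_ostai("site_sds too small for the configured signal and shared noise",
               "ostai_domain_error")
  }
  invisible(cfg)
}

# Variance of the linear T-score signal implied by the config: quadratic
# form over the continuous covariates (per-10-unit scale) plus independent
# Bernoulli contributions.
eta_variance <- function(cfg) {
  b <- cfg$coefs[.cont_vars]
  S <- diag(cfg$sds / 10) %*% cfg$corr %*% diag(cfg$sds / 10)
  v_cont <- as.numeric(t(b) %*% S %*% b)
  p <- cfg$prevalences
  v_bin <- sum(cfg$coefs[names(p)]^2 * p * (1 - p))
  v_cont + v_bin
}

# Draw n rows of covariates + latent signal + per-site T-scores (without
# the calibration shift). Consumes the current RNG stream.
draw_raw_cohort <- function(n, cfg) {
  Sigma <- diag(cfg$sds) %*% cfg$corr %*% diag(cfg$sds)
  X <- matrix(NA_real_, n, 4, dimnames = list(NULL, .cont_vars))
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- MASS::mvrnorm(length(need), cfg$means, Sigma)
    if (length(need) == 1) draw <- matrix(draw, 1)
    z <- sweep(sweep(draw, 2, cfg$means), 2, cfg$sds, "/")
    ok <- rowSums(abs(z) > cfg$trunc_sd) == 0
    X[need[ok], ] <- draw[ok, , drop = FALSE]
    need <- need[!ok]
  }
  # a menopause age drawn above the current age is recorded at the current
  # age (point-mass clamp; keeps the age and weight marginals intact)
  X[, "menopause_age"] <- pmin(X[, "menopause_age"], X[, "age"])
  bin <- vapply(names(cfg$prevalences),
                function(v) rbinom(n, 1L, cfg$prevalences[[v]]),
                integer(n))
  if (n == 1) bin <- matrix(bin, 1, dimnames = list(NULL, names(cfg$prevalences)))
  eta <- as.numeric((X / 10) %*% cfg$coefs[.cont_vars]) +
    as.numeric(bin %*% cfg$coefs[colnames(bin)])
  e_sd <- sqrt(cfg$site_sds^2 - eta_variance(cfg) - cfg$shared_noise_sd^2)
  u <- rnorm(n, 0, cfg$shared_noise_sd)
  centered_eta <- eta - as.numeric((cfg$means / 10) %*% cfg$coefs[.cont_vars]) -
    sum(cfg$coefs[names(cfg$prevalences)] * cfg$prevalences)
  tmat <- vapply(seq_along(cfg$site_means), function(s) {
    cfg$site_means[[s]] + centered_eta + u + rnorm(n, 0, e_sd[[s]])
  }, numeric(n))
  if (n == 1) tmat <- matrix(tmat, 1)
  colnames(tmat) <- c("t_lumbar", "t_femoral_neck", "t_total_hip")
  list(X = X, bin = bin, eta = eta, tmat = tmat,
       lowest = pmin(tmat[, 1], tmat[, 2], tmat[, 3]))
}

# Intercept shift that makes P(lowest T-score <= -2.5) hit the target,
# solved by direct quantile inversion on a large calibration sample.
calibrate_shift <- function(cfg, seed) {
  cal_seed <- (as.numeric(seed) * 48271 + 11) %% 2147483647
  set.seed(as.integer(cal_seed))
  raw <- draw_raw_cohort(cfg$n_cal, cfg)
  unname(-2.5 - quantile(raw$lowest, cfg$target_prevalence))
}

#' Generate a synthetic study-like cohort
#'
#' Draws a seeded cohort of postmenopausal women. Continuous demographics
#' come from a correlated multivariate normal truncated at `trunc_sd` SDs;
#' risk factors are Bernoulli draws subsequently masked to missing,
#' independently per question, at the configured questionnaire response
#' rates; each site T-score is a linear function of the (fully observed)
#' covariates plus shared and site-specific Gaussian noise, with site
#' intercepts shifted by a calibration constant so that the prevalence of a
#' lowest T-score at or below -2.5 matches the configured target. The
#' generating coefficients and per-participant latent signal are returned
#' as ground truth.
#'
#' @param n cohort size.
#' @param seed integer seed; the same seed reproduces the cohort exactly
#'   (the generator pins the Mersenne-Twister/Inversion RNG).
#' @param config a [generator_config()].
#' @return A cohort tibble in the [cohort_schema()] layout with attributes
#'   `truth` (see [cohort_truth()]) and `config`.
#' @export
generate_cohort <- function(n, seed, config = generator_config()) {
  if (n < 1) stop_ostai("n must be at least 1", "ostai_domain_error")
  old <- globalenv()$.Random.seed
  old_kind <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  shift <- calibrate_shift(config, seed)
  set.seed(as.integer(seed))
  raw <- draw_raw_cohort(n, config)
  tmat <- raw$tmat + shift
  bin <- raw$bin
  for (v in colnames(bin)) {
    mask <- runif(n) > config$response_rates[[v]]
    bin[mask, v] <- NA_integer_
  }
  cohort <- tibble(
    id = sprintf("S%06d", seq_len(n)),
    sex = "female", menopausal = "post",
    age = raw$X[, "age"], height = raw$X[, "height"],
    weight = raw$X[, "weight"], menopause_age = raw$X[, "menopause_age"],
    t_lumbar = tmat[, "t_lumbar"], t_femoral_neck = tmat[, "t_femoral_neck"],
    t_total_hip = tmat[, "t_total_hip"]
  )
  cohort <- dplyr::bind_cols(cohort, as_tibble(bin))
  attr(cohort, "truth") <- list(
    coefs = config$coefs,
    intercept_shift = shift,
    site_means = config$site_means,
    shared_noise_sd = config$shared_noise_sd,
    site_noise_sds = sqrt(config$site_sds^2 - eta_variance(config) -
                            config$shared_noise_sd^2),
    eta = raw$eta,
    seed = seed
  )
  attr(cohort, "config") <- config
  cohort
}

#' Ground truth of a generated cohort
#'
#' @param data a cohort from [generate_cohort()].
#' @return The list of generating coefficients, intercept shift, noise SDs
#'   and per-participant latent signal stored at generation time.
#' @export
cohort_truth <- function(data) attr(data, "truth")

#' Inject QC pathologies into a cohort
#'
#' Adds or corrupts rows so that the exclusion pipeline has known targets:
#' appended male rows, appended premenopausal rows, missing T-scores
#' injected into existing rows, and extreme covariate values (the variable
#' mean plus `extreme_sd` SDs) injected into existing rows. A manifest of
#' the affected ids and the pathology applied is attached.
#'
#' @param data cohort tibble.
#' @param n_male,n_premenopausal numbers of rows to append.
#' @param missing_bmd fraction (if < 1) or count of existing rows that lose
#'   one randomly chosen site T-score.
#' @param n_extreme number of existing rows given an extreme age.
#' @param extreme_sd how many SDs beyond the mean an injected extreme value
#'   lies (default 8).
#' @param seed integer seed.
#' @return The modified cohort with attribute `manifest` (tibble `id`,
#'   `pathology`), retrievable with `attr(x, "manifest")`.
#' @export
inject_pathologies <- function(data, n_male = 0, n_premenopausal = 0,
                               missing_bmd = 0, n_extreme = 0,
                               extreme_sd = 8, seed = 1) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  manifest <- list()
  orig <- data
  make_rows <- function(k, prefix) {
    rows <- orig[sample(nrow(orig), k, replace = TRUE), ]
    rows$id <- sprintf("%s%04d", prefix, seq_len(k))
    rows
  }
  if (n_male > 0) {
    rows <- make_rows(n_male, "INJM")
    rows$sex <- "male"
    data <- dplyr::bind_rows(data, rows)
    manifest$male <- tibble(id = rows$id, pathology = "male")
  }
  if (n_premenopausal > 0) {
    rows <- make_rows(n_premenopausal, "INJP")
    rows$menopausal <- "pre"
    data <- dplyr::bind_rows(data, rows)
    manifest$pre <- tibble(id = rows$id, pathology = "premenopausal")
  }
  if (anyDuplicated(data$id)) {
    stop_ostai("injected ids collide with existing ids", "ostai_domain_error")
  }
  eligible <- which(data$sex == "female" & data$menopausal == "post")
  if (missing_bmd > 0) {
    k <- if (missing_bmd < 1) round(missing_bmd * length(eligible)) else missing_bmd
    k <- min(k, length(eligible))
    idx <- sample(eligible, k)
    site <- sample(.t_score_cols, k, replace = TRUE)
    for (i in seq_len(k)) data[[site[i]]][idx[i]] <- NA_real_
    manifest$bmd <- tibble(id = data$id[idx], pathology = "missing_bmd")
    eligible <- setdiff(eligible, idx)
  }
  if (n_extreme > 0) {
    k <- min(n_extreme, length(eligible))
    idx <- sample(eligible, k)
    mu <- mean(data$age, na.rm = TRUE)
    s <- sd(data$age, na.rm = TRUE)
    data$age[idx] <- mu + extreme_sd * s
    manifest$extreme <- tibble(id = data$id[idx], pathology = "extreme_value")
  }
  attr(data, "manifest") <- dplyr::bind_rows(manifest) %||%
    tibble(id = character(), pathology = character())
  data
}
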