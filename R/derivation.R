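# Resolve the regression response: the lowest T-score across the three
# measured sites (the scale on which the case definition operates) or a
# single named site.
get_response <- function(data, response = c("lowest", "lumbar", "femoral_neck", "total_hip")) {
  response <- match.arg(response)
  if (response == "lowest") {
    if (!"lowest_t" %in% names(data)) data <- classify_osteoporosis(data)
    return(data$lowest_t)
  }
  data[[c(lumbar = "t_lumbar", femoral_neck = "t_femoral_neck",
          total_hip = "t_total_hip")[response]]]
}

#' Univariate screen of candidate risk factors
#'
#' Fits one simple linear regression per candidate FRAX-style risk factor,
#' with a BMD T-score response (the lowest of the three sites by default).
#' Continuous variables enter per 10 units (10 years, 10 cm, 10 kg) so that
#' coefficients are on the increment scale used for index weighting;
#' binaries enter as yes (1) versus no (0), with unanswered items excluded
#' from that factor's fit. Candidates with `p < alpha` are flagged as
#' retained for the multivariable stage.
#'
#' @param data cohort tibble (post-QC).
#' @param alpha retention threshold on the p-value, in (0, 1); default 0.05.
#' @param response `"lowest"` (default), `"lumbar"`, `"femoral_neck"` or
#'   `"total_hip"`.
#' @param candidates character vector of candidate columns.
#' @return A tibble with one row per candidate: `variable`, `beta`, `se`,
#'   `p`, `n` (complete cases used) and `retained`. A zero-variance
#'   candidate is flagged not retained with `NA` estimates and a warning.
#' @export
univariate_screen <- function(data, alpha = 0.05,
                              response = "lowest",
                              candidates = c(.cont_vars, .binary_vars)) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop_ostai("alpha must lie in (0, 1]", "ostai_domain_error")
  }
  y <- get_response(data, response)
  purrr::map_dfr(candidates, function(v) {
    x <- scale_covariate(data, v)
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3 || var(x[ok]) == 0) {
      warn(paste0("candidate '", v, "' has no variance; skipped"))
      return(tibble(variable = v, beta = NA_real_, se = NA_real_,
                    p = NA_real_, n = sum(ok), retained = FALSE))
    }
    fit <- summary(lm(y[ok] ~ x[ok]))$coefficients
    tibble(variable = v, beta = fit[2, 1], se = fit[2, 2], p = fit[2, 4],
           n = sum(ok), retained = fit[2, 4] < alpha)
  })
}

#' Multivariable regression of a T-score on selected risk factors
#'
#' Ordinary least squares of the response T-score on all listed variables
#' simultaneously, with the same per-10-unit scaling as
#' [univariate_screen()] and complete-case rows for the listed variable
#' set.
#'
#' @inheritParams univariate_screen
#' @param variables character vector of at least two cohort columns.
#' @return A tibble with columns `variable`, `beta`, `se`, `p`, carrying
#'   attributes `n`, `intercept`, `sigma` and `r_squared`.
#' @export
fit_multivariable <- function(data, variables, response = "lowest") {
  if (length(variables) < 2) {
    stop_ostai("at least two variables are required", "ostai_domain_error")
  }
  y <- get_response(data, response)
  X <- purrr::map_dfc(setNames(variables, variables),
                      function(v) scale_covariate(data, v))
  ok <- complete.cases(X) & !is.na(y)
  if (sum(ok) < 10 * length(variables)) {
    stop_ostai(paste0("insufficient complete cases (", sum(ok), ") for ",
                      length(variables), " variables"), "ostai_domain_error")
  }
  df <- cbind(.y = y[ok], X[ok, , drop = FALSE])
  fit <- lm(reformulate(sprintf("`%s`", variables), ".y"), data = df)
  if (any(is.na(coef(fit)))) {
    collinear <- names(coef(fit))[is.na(coef(fit))]
    stop_ostai(paste0("rank-deficient design; collinear terms: ",
                      paste(collinear, collapse = ", ")), "ostai_domain_error")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  out <- tibble(variable = variables,
                beta = unname(co[-1, 1]), se = unname(co[-1, 2]),
                p = unname(co[-1, 4]))
  attr(out, "n") <- sum(ok)
  attr(out, "intercept") <- co[1, 1]
  attr(out, "sigma") <- sm$sigma
  attr(out, "r_squared") <- sm$r.squared
  out
}

#' Build an integer-weighted risk index from regression coefficients
#'
#' Converts the coefficients of one multivariable T-score model into signed
#' integer index weights by dividing each coefficient by a scale anchor and
#' rounding. Two anchor policies are available:
#'
#' * `"age_5yr"` (default): the points-system convention of Sullivan and
#'   D'Agostino used by Framingham-style scores -- one index unit is the
#'   T-score change associated with 5 years of age, i.e. half the per-decade
#'   age coefficient. This is stable under resampling because it anchors on
#'   the most precisely estimated coefficient, and it gives age a weight of
#'   -2 per decade by construction. When age is not among the fitted
#'   variables the policy falls back to `"min_beta"`.
#' * `"min_beta"`: one index unit is the smallest absolute coefficient in
#'   the model, so the weakest retained factor carries weight +/-1.
#'
#' Both policies reproduce the published OSTAi index-weight column from its
#' development-model coefficients. Weights carry the sign of the
#' coefficient and are never zero: a coefficient smaller than half the
#' anchor receives the minimal weight of +/-1 so that every retained
#' variable contributes.
#'
#' @param fits a tibble with columns `variable`, `beta` (and optionally
#'   `se`, `p`), all from a single multivariable model.
#' @param anchor `"age_5yr"` or `"min_beta"`.
#' @param rounding `"nearest"` (halves away from zero, default) or
#'   `"truncate"`.
#' @param cutoff optional integer screening cutoff to store in the model.
#' @return An object of class `index_model`: a list with elements
#'   `variables`, `weights` (named integers), `increments` (10 for
#'   continuous variables, 1 for binaries), `referents`, `scale_anchor`,
#'   `anchor`, `rounding`, `cutoff` and `fits`.
#' @examples
#' fits <- tibble::tibble(
#'   variable = c("age", "height", "weight", "menopause_age",
#'                "previous_fracture", "current_smoking", "glucocorticoids"),
#'   beta = c(-0.364, 0.175, 0.343, 0.161, -0.228, -0.293, -0.198)
#' )
#' make_index_weights(fits)$weights
#' @export
make_index_weights <- function(fits, anchor = c("age_5yr", "min_beta"),
                               rounding = c("nearest", "truncate"),
                               cutoff = NA_integer_) {
  anchor <- match.arg(anchor)
  rounding <- match.arg(rounding)
  stopifnot(all(c("variable", "beta") %in% names(fits)))
  beta <- setNames(fits$beta, fits$variable)
  if (any(beta == 0)) {
    stop_ostai("coefficients of exactly zero cannot be weighted",
               "ostai_domain_error")
  }
  scale_anchor <- if (anchor == "age_5yr" && "age" %in% names(beta)) {
    abs(beta[["age"]]) / 2
  } else {
    min(abs(beta))
  }
  w <- apply_rounding(beta / scale_anchor, rounding)
  w[w == 0] <- sign(beta[w == 0])
  new_index_model(
    variables = fits$variable,
    weights = setNames(as.integer(w), fits$variable),
    scale_anchor = unname(scale_anchor),
    anchor = anchor, rounding = rounding,
    cutoff = as.integer(cutoff), fits = fits
  )
}

new_index_model <- function(variables, weights, scale_anchor, anchor,
                            rounding, cutoff, fits) {
  structure(
    list(
      variables = variables,
      weights = weights,
      increments = default_increments(variables),
      referents = default_referents(variables),
      scale_anchor = scale_anchor,
      anchor = anchor,
      rounding = rounding,
      cutoff = cutoff,
      fits = fits
    ),
    class = "index_model"
  )
}

#' @export
print.index_model <- function(x, ...) {
  cat("<index_model> ", length(x$variables), " variables, anchor ",
      x$anchor, " (", signif(x$scale_anchor, 3), ")\n", sep = "")
  df <- tidy(x)
  print(as.data.frame(df), row.names = FALSE)
  if (!is.na(x$cutoff)) cat("screening cutoff: score <", x$cutoff, "is positive\n")
  invisible(x)
}

#' @rdname make_index_weights
#' @param x an `index_model`.
#' @param ... unused.
#' @export
tidy.index_model <- function(x, ...) {
  out <- tibble(
    variable = x$variables,
    weight = unname(x$weights[x$variables]),
    increment = unname(x$increments[x$variables]),
    referent = unname(x$referents[x$variables])
  )
  extra <- intersect(c("beta", "se", "p"), names(x$fits))
  dplyr::left_join(out, x$fits[, c("variable", extra)], by = "variable")
}

#' @rdname make_index_weights
#' @export
glance.index_model <- function(x, ...) {
  tibble(
    n_variables = length(x$variables),
    scale_anchor = x$scale_anchor,
    anchor = x$anchor,
    rounding = x$rounding,
    cutoff = x$cutoff
  )
}

#' Score a cohort with an index model
#'
#' The raw index score of a participant is the weighted sum of increments
#' from the referent values, `sum_v weight_v * (x_v - referent_v) /
#' increment_v`; the integer index value is the rounded raw score. For the
#' two-variable model with weights (-2, +2) for age and weight per 10 units
#' and referents of 50, this reduces exactly to the OSTAi formula
#' `0.2 * (weight - age)`.
#'
#' @param data cohort tibble.
#' @param model an `index_model`.
#' @return `data` with columns `index_raw` and `index_value` appended; rows
#'   missing any model variable get `NA`.
#' @export
score_index <- function(data, model) {
  raw <- rep(0, nrow(data))
  for (v in model$variables) {
    raw <- raw + model$weights[[v]] *
      (data[[v]] - model$referents[[v]]) / model$increments[[v]]
  }
  data$index_raw <- raw
  data$index_value <- as.integer(apply_rounding(raw, model$rounding))
  data
}

# Raw weighted sum used inside the reduction loop (no referent shift or
# rounding; both are irrelevant for rank-based discrimination).
weighted_sum <- function(data, model) {
  s <- rep(0, nrow(data))
  for (v in model$variables) {
    s <- s + model$weights[[v]] * scale_covariate(data, v)
  }
  s
}

#' Backward item reduction under an AUC-retention tolerance
#'
#' Simplifies an index model by backward elimination: at each step the
#' variable whose removal least decreases the AUC for osteoporosis is
#' dropped, the regression is refit on the remaining variables and the
#' integer weights recomputed (same anchor policy), as long as the AUC of
#' the reduced model stays within `tol_auc` of the full starting model.
#' All comparisons are made on a fixed evaluation set -- the rows that the
#' full model can score (complete cases for its variable set) -- so that
#' candidate models are compared on identical participants; each refit
#' itself uses the complete cases of its own variable set.
#'
#' @param data cohort tibble with T-scores (status is derived with
#'   [classify_osteoporosis()] when absent).
#' @param model the starting `index_model`.
#' @param tol_auc maximum tolerated loss of AUC relative to the full model
#'   (default 0.01).
#' @param response response T-score passed to the refits.
#' @return The reduced `index_model` (cutoff preserved), with attribute
#'   `trace`: a tibble recording, per step, the variable dropped and the
#'   AUC of the model after the drop. Retrieve it with
#'   `attr(model, "trace")`.
#' @export
item_reduction <- function(data, model, tol_auc = 0.01, response = "lowest") {
  if (tol_auc < 0) stop_ostai("tol_auc must be >= 0", "ostai_domain_error")
  if (length(model$variables) < 2) {
    warn("model has fewer than 2 variables; nothing to reduce")
    return(model)
  }
  if (!"osteoporotic" %in% names(data)) data <- classify_osteoporosis(data)
  eval_set <- data[complete.cases(data[, model$variables, drop = FALSE]) &
                     !is.na(data$osteoporotic), , drop = FALSE]
  full_auc <- auc_mw(weighted_sum(eval_set, model), eval_set$osteoporotic)
  trace <- list(tibble(step = 0L, dropped = NA_character_,
                       n_variables = length(model$variables), auc = full_auc))
  current <- model
  step <- 0L
  while (length(current$variables) > 1) {
    candidates <- purrr::map(current$variables, function(v) {
      remaining <- setdiff(current$variables, v)
      refit <- if (length(remaining) >= 2) {
        fit_multivariable(data, remaining, response)
      } else {
        uni <- univariate_screen(data, alpha = 1, response = response,
                                 candidates = remaining)
        uni[, c("variable", "beta", "se", "p")]
      }
      cand <- make_index_weights(refit, anchor = current$anchor,
                                 rounding = current$rounding,
                                 cutoff = current$cutoff)
      list(model = cand,
           auc = auc_mw(weighted_sum(eval_set, cand), eval_set$osteoporotic))
    })
    aucs <- purrr::map_dbl(candidates, "auc")
    best <- which.max(aucs)
    if (full_auc - aucs[best] > tol_auc) break
    step <- step + 1L
    dropped <- current$variables[best]
    current <- candidates[[best]]$model
    trace[[length(trace) + 1]] <- tibble(
      step = step, dropped = dropped,
      n_variables = length(current$variables), auc = aucs[best]
    )
  }
  attr(current, "trace") <- dplyr::bind_rows(trace)
  current
}

#' Select the screening cutoff maximising Youden's J
#'
#' Scores the cohort with the index model, then evaluates every integer
#' cutoff in the observed score range with positivity defined as
#' `score < cutoff`, and returns the cutoff maximising Youden's J
#' (sensitivity + specificity - 1). Ties are broken toward the
#' higher-sensitivity (higher) cutoff.
#'
#' @inheritParams item_reduction
#' @return An object of class `cutoff_selection`: a list with `cutoff`,
#'   `j`, `sensitivity`, `specificity` and the full `sweep` tibble.
#' @export
select_cutoff <- function(data, model) {
  if (!"osteoporotic" %in% names(data)) data <- classify_osteoporosis(data)
  scored <- score_index(data, model)
  ok <- !is.na(scored$index_value) & !is.na(scored$osteoporotic)
  v <- scored$index_value[ok]
  y <- scored$osteoporotic[ok]
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop_ostai("cohort is degenerate: both osteoporotic and non-osteoporotic participants are required",
               "ostai_domain_error")
  }
  cutoffs <- seq(min(v), max(v))
  sweep <- purrr::map_dfr(cutoffs, function(ct) {
    pos <- v < ct
    tibble(cutoff = ct,
           sensitivity = sum(pos & y) / n_pos,
           specificity = sum(!pos & !y) / n_neg)
  })
  sweep$j <- sweep$sensitivity + sweep$specificity - 1
  best <- sweep[abs(sweep$j - max(sweep$j)) < 1e-12, , drop = FALSE]
  best <- best[best$sensitivity == max(best$sensitivity), , drop = FALSE]
  best <- best[which.max(best$cutoff), , drop = FALSE]
  if (max(sweep$j) < 0.05) {
    warn("Youden profile is nearly flat; the selected cutoff is weakly determined")
  }
  structure(
    list(cutoff = as.integer(best$cutoff), j = best$j,
         sensitivity = best$sensitivity, specificity = best$specificity,
         sweep = sweep),
    class = "cutoff_selection"
  )
}

#' @export
print.cutoff_selection <- function(x, ...) {
  cat("<cutoff_selection> cutoff", x$cutoff,
      sprintf("(J = %.3f, sensitivity %.1f%%, specificity %.1f%%)\n",
              x$j, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' @export
tidy.cutoff_selection <- function(x, ...) x$sweep

#' Derive a screening index from a cohort
#'
#' Runs the complete index-derivation pipeline: univariate screen of all
#' candidate risk factors at `alpha`, multivariable fit of the retained
#' set, integer index weighting, backward item reduction under `tol_auc`,
#' and Youden-optimal integer cutoff selection for the reduced index.
#'
#' @inheritParams univariate_screen
#' @inheritParams item_reduction
#' @param anchor,rounding passed to [make_index_weights()].
#' @return The reduced `index_model` with its selected `cutoff`, carrying
#'   attributes `screen` (univariate table), `full_fits` (multivariable
#'   table), `trace` (reduction trace) and `cutoff_selection`.
#' @export
derive_index <- function(data, alpha = 0.05, tol_auc = 0.01,
                         anchor = "age_5yr", rounding = "nearest",
                         response = "lowest",
                         candidates = c(.cont_vars, .binary_vars)) {
  if (!"osteoporotic" %in% names(data)) data <- classify_osteoporosis(data)
  screen <- univariate_screen(data, alpha, response, candidates)
  retained <- screen$variable[screen$retained]
  if (length(retained) < 2) {
    stop_ostai("fewer than two candidates retained by the univariate screen",
               "ostai_domain_error")
  }
  fits <- fit_multivariable(data, retained, response)
  full <- make_index_weights(fits, anchor = anchor, rounding = rounding)
  reduced <- item_reduction(data, full, tol_auc, response)
  sel <- select_cutoff(data, reduced)
  reduced$cutoff <- sel$cutoff
  attr(reduced, "screen") <- screen
  attr(reduced, "full_fits") <- fits
  attr(reduced, "cutoff_selection") <- sel
  reduced
}
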