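test_that("the published development-model coefficients reproduce the published index weights", {
  fits <- published_betas()
  for (anchor in c("age_5yr", "min_beta")) {
    model <- make_index_weights(fits, anchor = anchor)
    expect_equal(unname(model$weights[fits$variable]), published_weights,
                 info = anchor)
  }
})

test_that("index weights are scale invariant and match a one-line recomputation", {
  set.seed(14)
  for (i in 1:200) {
    k <- sample(2:8, 1)
    beta <- runif(k, -0.6, 0.6)
    beta[abs(beta) < 0.01] <- 0.05
    fits <- tibble::tibble(variable = paste0("v", seq_len(k)), beta = beta)
    m <- make_index_weights(fits, anchor = "min_beta")
    # independent recomputation: round(beta / min |beta|), halves away from 0
    r <- beta / min(abs(beta))
    oracle <- trunc(r + 0.5 * sign(r))
    expect_equal(unname(m$weights), as.integer(oracle))
    # scale invariance
    c_pos <- runif(1, 0.1, 10)
    m2 <- make_index_weights(dplyr::mutate(fits, beta = beta * c_pos),
                             anchor = "min_beta")
    expect_equal(m2$weights, m$weights)
  }
  expect_error(make_index_weights(tibble::tibble(variable = "a", beta = 0)),
               class = "ostai_error")
})

test_that("univariate screen retains truly associated variables and honours alpha", {
  cfg_null <- generator_config(coefs = c(
    age = -0.364, height = 0, weight = 0, menopause_age = 0,
    previous_fracture = 0, parent_hip_fracture = 0, current_smoking = 0,
    glucocorticoids = 0, rheumatoid_arthritis = 0,
    secondary_osteoporosis = 0, alcohol_3plus_units = 0
  ))
  co <- classify_osteoporosis(generate_cohort(5000, seed = 2, config = cfg_null))
  screen <- univariate_screen(co)
  expect_true(screen$retained[screen$variable == "age"])
  # truly-null binaries should mostly be dropped at alpha = 0.05
  nulls <- screen$retained[screen$variable %in%
                             c("parent_hip_fracture", "rheumatoid_arthritis",
                               "secondary_osteoporosis", "alcohol_3plus_units")]
  expect_lte(sum(nulls), 1)

  all_in <- univariate_screen(co, alpha = 1)
  expect_true(all(all_in$retained[!is.na(all_in$beta)]))

  co$glucocorticoids <- 0L
  expect_warning(s2 <- univariate_screen(co), "no variance")
  expect_false(s2$retained[s2$variable == "glucocorticoids"])
})

test_that("the multivariable fit recovers the generating coefficients within 3 SE", {
  co <- classify_osteoporosis(generate_cohort(20000, seed = 31))
  truth <- cohort_truth(co)$coefs
  vars <- c("age", "height", "weight", "menopause_age",
            "previous_fracture", "current_smoking", "glucocorticoids")
  fits <- fit_multivariable(co, vars)
  for (i in seq_len(nrow(fits))) {
    expect_lt(abs(fits$beta[i] - truth[[fits$variable[i]]]), 3 * fits$se[i])
  }
  expect_gt(attr(fits, "n"), 10 * length(vars))
})

test_that("a noise-free response equal to one covariate is recovered exactly", {
  co <- generate_cohort(500, seed = 4)
  co$t_lumbar <- co$age  # response identical to age on the natural scale
  fits <- fit_multivariable(co, c("age", "weight"), response = "lumbar")
  expect_equal(fits$beta[fits$variable == "age"], 10, tolerance = 1e-8)
  expect_equal(fits$beta[fits$variable == "weight"], 0, tolerance = 1e-8)
  expect_equal(attr(fits, "r_squared"), 1, tolerance = 1e-8)
})

test_that("multivariable fit rejects collinear and undersized designs", {
  co <- generate_cohort(300, seed = 6)
  co$height <- co$weight  # perfect collinearity
  expect_error(fit_multivariable(co, c("age", "height", "weight")),
               class = "ostai_error")
  expect_error(fit_multivariable(co[1:15, ], c("age", "weight")),
               class = "ostai_error")
  expect_error(fit_multivariable(co, "age"), class = "ostai_error")
})

test_that("a derived two-variable age/weight model scores identically to the OSTAi formula", {
  model <- make_index_weights(tibble::tibble(
    variable = c("age", "weight"), beta = c(-0.382, 0.386)
  ))
  expect_equal(unname(model$weights), c(-2L, 2L))
  set.seed(12)
  d <- tibble::tibble(age = runif(500, 45, 95), weight = runif(500, 35, 95))
  scored <- score_index(d, model)
  direct <- ostai_score(d)
  expect_equal(scored$index_raw, direct$ostai_raw, tolerance = 1e-12)
  expect_equal(scored$index_value, direct$ostai_value)
})

test_that("item reduction keeps informative variables at zero tolerance and warns on single-variable models", {
  cfg <- generator_config(coefs = c(
    age = -0.364, height = 0, weight = 0.343, menopause_age = 0,
    previous_fracture = 0, parent_hip_fracture = 0, current_smoking = 0,
    glucocorticoids = 0, rheumatoid_arthritis = 0,
    secondary_osteoporosis = 0, alcohol_3plus_units = 0
  ))
  co <- classify_osteoporosis(generate_cohort(8000, seed = 17, config = cfg))
  fits <- fit_multivariable(co, c("age", "weight"))
  model <- make_index_weights(fits)
  kept <- item_reduction(co, model, tol_auc = 0)
  expect_setequal(kept$variables, c("age", "weight"))

  single <- make_index_weights(tibble::tibble(variable = c("age", "weight"),
                                              beta = c(-0.364, 0.343)))
  single$variables <- "age"
  expect_warning(out <- item_reduction(co, single), "fewer than 2")
})

test_that("reduction from the full model ends at age and weight when only they carry signal", {
  cfg <- generator_config(coefs = c(
    age = -0.364, height = 0, weight = 0.343, menopause_age = 0,
    previous_fracture = 0, parent_hip_fracture = 0, current_smoking = 0,
    glucocorticoids = 0, rheumatoid_arthritis = 0,
    secondary_osteoporosis = 0, alcohol_3plus_units = 0
  ))
  for (s in 1:3) {
    co <- classify_osteoporosis(generate_cohort(10000, seed = 100 + s,
                                                config = cfg))
    model <- derive_index(co)
    expect_setequal(model$variables, c("age", "weight"))
    expect_equal(unname(model$weights[c("age", "weight")]), c(-2L, 2L))
    trace <- attr(model, "trace")
    expect_equal(trace$n_variables[1] - nrow(trace) + 1,
                 length(model$variables))
  }
})

test_that("cutoff selection maximises Youden's J with ties broken upward", {
  toy <- cohort_of(
    purrr::map_dfr(1:10, ~participant(paste0("c", .x), t_lumbar = -3,
                                      age = 80, weight = 50)),
    purrr::map_dfr(1:10, ~participant(paste0("n", .x), age = 50, weight = 50))
  )
  toy <- classify_osteoporosis(toy)
  model <- make_index_weights(tibble::tibble(variable = c("age", "weight"),
                                             beta = c(-0.364, 0.343)))
  # cases score -6, controls 0: every cutoff in {-5,...,0} separates
  sel <- select_cutoff(toy, model)
  expect_equal(sel$j, 1)
  expect_equal(sel$cutoff, 0L)

  expect_error(select_cutoff(dplyr::filter(toy, osteoporotic), model),
               class = "ostai_error")
})

test_that("cutoff selection equals exhaustive search and warns on a flat profile", {
  co <- classify_osteoporosis(generate_cohort(12000, seed = 77))
  model <- make_index_weights(tibble::tibble(variable = c("age", "weight"),
                                             beta = c(-0.382, 0.386)))
  sel <- select_cutoff(co, model)
  # independent exhaustive maximisation over all integer cutoffs
  sc <- score_index(co, model)
  best_j <- -Inf; best_ct <- NA; best_sens <- -Inf
  for (ct in seq(min(sc$index_value), max(sc$index_value))) {
    pos <- sc$index_value < ct
    sens <- sum(pos & co$osteoporotic) / sum(co$osteoporotic)
    spec <- sum(!pos & !co$osteoporotic) / sum(!co$osteoporotic)
    j <- sens + spec - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && sens > best_sens) ||
        (abs(j - best_j) <= 1e-12 && sens == best_sens && ct > best_ct)) {
      best_j <- j; best_ct <- ct; best_sens <- sens
    }
  }
  expect_equal(sel$cutoff, best_ct)
  expect_equal(sel$j, best_j, tolerance = 1e-12)

  # a score independent of status gives a near-flat profile
  co2 <- co
  set.seed(5)
  co2$age <- sample(co2$age)
  co2$weight <- sample(co2$weight)
  expect_warning(sel2 <- select_cutoff(co2, model), "flat")
  expect_lt(sel2$j, 0.05)
})

test_that("tidy and glance summarise an index model", {
  model <- make_index_weights(published_betas())
  td <- tidy(model)
  expect_equal(nrow(td), 7)
  expect_equal(td$weight, published_weights)
  expect_equal(td$increment[td$variable == "age"], 10)
  gl <- glance(model)
  expect_equal(gl$n_variables, 7)
  expect_equal(gl$anchor, "age_5yr")
  expect_equal(gl$scale_anchor, 0.182)
})
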