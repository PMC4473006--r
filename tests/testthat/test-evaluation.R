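test_that("confusion counts match a per-row tally and guard their preconditions", {
  set.seed(19)
  pos <- runif(300) < 0.4
  truth <- runif(300) < 0.45
  m <- confusion_counts(pos, truth)
  oracle <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in 1:300) {
    cell <- if (pos[i] && truth[i]) "tp" else if (pos[i]) "fp"
            else if (truth[i]) "fn" else "tn"
    oracle[cell] <- oracle[cell] + 1
  }
  expect_equal(unlist(m), oracle)
  expect_equal(sum(unlist(m)), 300)

  all_pos <- confusion_counts(rep(TRUE, 10), truth[1:10])
  expect_equal(all_pos$fn + all_pos$tn, 0)
  expect_error(confusion_counts(pos, truth[-1]), class = "ostai_error")
  expect_error(confusion_counts(c(TRUE, NA), c(TRUE, FALSE)),
               class = "ostai_error")
})

test_that("screening metrics reproduce the published fractions", {
  m1 <- diag_metrics(3674, 2719, 1353, 4429)
  expect_equal(m1$estimate, c(0.731, 0.620, 0.575, 0.766), tolerance = 5e-4)
  m2 <- diag_metrics(3936, 3813, 1091, 3335)
  expect_equal(m2$estimate, c(0.783, 0.467, 0.508, 0.754), tolerance = 5e-4)
  perfect <- diag_metrics(1, 0, 0, 1)
  expect_equal(perfect$estimate, rep(1, 4))
  undef <- diag_metrics(0, 0, 5, 5)
  expect_true(is.na(undef$estimate[undef$metric == "ppv"]))
  expect_false(anyNA(undef$estimate[undef$metric %in% c("sensitivity", "npv")]))
})

test_that("trapezoidal AUC equals the pairwise concordance oracle", {
  set.seed(23)
  score <- sample(-12:8, 500, replace = TRUE)
  truth <- runif(500) < plogis(-0.3 * score - 1)
  if (!any(truth)) truth[1] <- TRUE
  roc <- roc_curve(score, truth)
  expect_equal(roc$auc, pairwise_auc(score, truth), tolerance = 1e-12)

  # perfect separation and the null case
  expect_equal(roc_curve(c(-5, -4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  set.seed(24)
  null_roc <- roc_curve(rnorm(10000), runif(10000) < 0.4)
  expect_gt(null_roc$auc, 0.48)
  expect_lt(null_roc$auc, 0.52)
  expect_error(roc_curve(1:5, rep(TRUE, 5)), class = "ostai_error")
})

test_that("ROC points are monotone and a binary rule's AUC is (sens+spec)/2", {
  set.seed(25)
  co <- classify_osteoporosis(generate_cohort(3000, seed = 55))
  rep_nof <- diagnostic_report(co, "nof2013")
  est <- setNames(rep_nof$metrics$estimate, rep_nof$metrics$metric)
  expect_equal(rep_nof$roc$auc,
               (est[["sensitivity"]] + est[["specificity"]]) / 2,
               tolerance = 1e-12)
  expect_equal(nrow(rep_nof$roc$points), 4)  # two segments + sentinels

  rep_ostai <- diagnostic_report(co, "ostai")
  pts <- rep_ostai$roc$points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
})

test_that("DeLong AUC and confidence interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(26)
  co <- ostai_score(classify_osteoporosis(generate_cohort(2000, seed = 91)))
  roc <- roc_curve(co$ostai_value, co$osteoporotic)
  ref <- pROC::roc(co$osteoporotic, co$ostai_value, direction = ">",
                   levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(roc$ci_low, ci[1], tolerance = 1e-6)
  expect_equal(roc$ci_high, ci[3], tolerance = 1e-6)
})

test_that("the Hanley-McNeil interval is available as a cross-check", {
  co <- ostai_score(classify_osteoporosis(generate_cohort(2000, seed = 92)))
  d <- roc_curve(co$ostai_value, co$osteoporotic, ci = "delong")
  h <- roc_curve(co$ostai_value, co$osteoporotic, ci = "hanley")
  expect_equal(d$auc, h$auc)
  expect_equal(d$se, h$se, tolerance = 0.25)  # same order, different estimator
  expect_lt(h$ci_low, h$auc)
  expect_gt(h$ci_high, h$auc)
})

test_that("category prevalence reproduces the published per-category fractions", {
  ref <- ostai_reference()$categories
  rows <- purrr::map_dfr(seq_len(nrow(ref)), function(i) {
    value <- c(low = 0L, medium = -2L, high = -5L)[[ref$category[i]]]
    tibble::tibble(
      ostai_value = rep(value, ref$total[i]),
      osteoporotic = rep(c(TRUE, FALSE),
                         c(ref$cases[i], ref$total[i] - ref$cases[i]))
    )
  })
  rows$ostai_category <- ostai_category(rows$ostai_value)
  out <- category_prevalence(rows)
  expect_equal(out$percent, c(23.4, 44.7, 70.0))
  expect_equal(sum(out$total), 12175)

  # all-low cohort reports empty categories as zeros
  low <- tibble::tibble(ostai_category = ostai_category(c(0L, 1L)),
                        osteoporotic = c(TRUE, FALSE))
  out2 <- category_prevalence(low)
  expect_equal(out2$total, c(2, 0, 0))
})

test_that("category tallies equal an independent per-row pass on a synthetic cohort", {
  co <- ostai_score(classify_osteoporosis(generate_cohort(3000, seed = 61)))
  out <- category_prevalence(co)
  for (lv in c("low", "medium", "high")) {
    rows <- co[co$ostai_category == lv, ]
    expect_equal(out$total[out$category == lv], nrow(rows))
    expect_equal(out$cases[out$category == lv], sum(rows$osteoporotic))
  }
  expect_equal(sum(out$total), nrow(co))
})

test_that("a rule compared with itself shows no difference and cohort mismatches error", {
  co <- classify_osteoporosis(generate_cohort(1500, seed = 71))
  a <- diagnostic_report(co, "ostai")
  cmp <- compare_rules(a, a)
  expect_equal(cmp$auc_diff, 0)
  expect_equal(cmp$p_value, 1)

  other <- classify_osteoporosis(generate_cohort(1500, seed = 72))
  b <- diagnostic_report(other, "ostai")
  expect_error(compare_rules(a, b), class = "ostai_error")
})

test_that("the paired DeLong p-value matches a permutation oracle", {
  co <- ostai_score(classify_osteoporosis(generate_cohort(400, seed = 81)))
  set.seed(82)
  # second rule: the same index plus noise, so the AUC difference is modest
  noisy <- co$ostai_raw + rnorm(nrow(co), 0, 3)
  a <- roc_curve(co$ostai_value, co$osteoporotic)
  b <- roc_curve(noisy, co$osteoporotic)
  rep_a <- list(roc = a, n = nrow(co), ids = NULL, rule = "a",
                matrix = NULL, metrics = diag_metrics(1, 1, 1, 1),
                prevalence = mean(co$osteoporotic), referral = 0.5,
                cutoff = NA, category_prevalence = NULL)
  rep_b <- rep_a
  rep_b$roc <- b
  class(rep_a) <- class(rep_b) <- "diagnostic_report"
  cmp <- compare_rules(rep_a, rep_b)

  auc_of <- function(s, y) {
    r <- rank(-s)
    n1 <- sum(y); n0 <- sum(!y)
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  obs <- abs(auc_of(co$ostai_value, co$osteoporotic) -
               auc_of(noisy, co$osteoporotic))
  set.seed(83)
  perm <- replicate(10000, {
    swap <- runif(nrow(co)) < 0.5
    s1 <- ifelse(swap, noisy, co$ostai_value)
    s2 <- ifelse(swap, co$ostai_value, noisy)
    abs(auc_of(s1, co$osteoporotic) - auc_of(s2, co$osteoporotic))
  })
  p_perm <- mean(perm >= obs)
  expect_lt(abs(cmp$p_value - p_perm), 0.05)
})

test_that("ostai reports carry referral burden, prevalence identity and category block", {
  co <- classify_osteoporosis(generate_cohort(2500, seed = 95))
  rep <- diagnostic_report(co, "ostai")
  m <- rep$matrix
  expect_equal((m$tp + m$fn) / rep$n, rep$prevalence)
  expect_equal((m$tp + m$fp) / rep$n, rep$referral)
  expect_false(is.null(rep$category_prevalence))
  gl <- glance(rep)
  expect_equal(gl$auc, rep$roc$auc)
  expect_equal(tidy(rep), rep$metrics)
})
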