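# Mann-Whitney AUC with ties counted one half, on the convention used
# throughout: a LOWER score means higher risk, so the AUC is the
# probability that a random case scores below a random control.
auc_mw <- function(score, truth) {
  ok <- !is.na(score) & !is.na(truth)
  score <- score[ok]
  truth <- truth[ok]
  risk <- -score
  r <- rank(risk)
  n1 <- as.numeric(sum(truth))
  n0 <- as.numeric(sum(!truth))
  if (n1 == 0 || n0 == 0) {
    stop_ostai("both classes must be present to compute an AUC",
               "ostai_domain_error")
  }
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values on the risk scale (higher risk = case).
# Returns V10 (per case) and V01 (per control); mean(V10) = AUC.
delong_placements <- function(risk, truth) {
  x <- risk[truth]
  y <- risk[!truth]
  m <- length(x)
  n <- length(y)
  r_all <- rank(c(x, y))
  r_x <- rank(x)
  r_y <- rank(y)
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

#' Confusion-matrix counts for a screening rule
#'
#' @param positive logical vector of screening decisions.
#' @param truth logical vector of osteoporosis status, aligned by
#'   participant.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(positive, truth) {
  if (length(positive) != length(truth)) {
    stop_ostai("decisions and statuses differ in length", "ostai_domain_error")
  }
  if (anyNA(positive) || anyNA(truth)) {
    stop_ostai("decisions and statuses must not contain missing values",
               "ostai_domain_error")
  }
  tibble(
    tp = sum(positive & truth), fp = sum(positive & !truth),
    fn = sum(!positive & truth), tn = sum(!positive & !truth)
  )
}

#' Screening-test metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each
#' reported with its exact count fraction. A metric whose denominator is
#' zero is reported as undefined (`NA`), never as zero.
#'
#' @param tp either the true-positive count, or a one-row data frame with
#'   columns `tp`, `fp`, `fn`, `tn` (e.g. from [confusion_counts()]).
#' @param fp,fn,tn counts (ignored when `tp` is a data frame).
#' @return A tibble with columns `metric`, `numerator`, `denominator`,
#'   `estimate` and `percent` (the estimate in percent, one decimal).
#' @examples
#' diag_metrics(3674, 2719, 1353, 4429)
#' @export
diag_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.data.frame(tp)) {
    counts <- tp
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  }
  num <- c(sensitivity = tp, specificity = tn, ppv = tp, npv = tn)
  den <- c(sensitivity = tp + fn, specificity = tn + fp,
           ppv = tp + fp, npv = tn + fn)
  est <- ifelse(den > 0, num / den, NA_real_)
  tibble(
    metric = names(num),
    numerator = unname(num), denominator = unname(den),
    estimate = unname(est), percent = fmt_pct(unname(est))
  )
}

#' ROC curve with AUC and confidence interval
#'
#' Sweeps a threshold over every observed score value (plus sentinels) with
#' positivity defined as `score < threshold` -- lower scores mean higher
#' risk -- and accumulates (false-positive rate, true-positive rate)
#' points. The AUC is computed by the trapezoidal rule, which for this
#' construction equals the Mann-Whitney concordance probability with ties
#' counted one half. The 95% confidence interval uses the DeLong variance
#' estimator by default; the Hanley-McNeil approximation is available for
#' cross-checking.
#'
#' @param score numeric score vector (lower = more at risk).
#' @param truth logical case status.
#' @param ci `"delong"` (default) or `"hanley"`.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `ostai_roc`: a list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`), `auc`, `se`, `ci_low`, `ci_high`,
#'   `ci_method`, `n_pos`, `n_neg`, and the score/status vectors used.
#' @export
roc_curve <- function(score, truth, ci = c("delong", "hanley"),
                      conf_level = 0.95) {
  ci <- match.arg(ci)
  ok <- !is.na(score) & !is.na(truth)
  score <- score[ok]
  truth <- as.logical(truth[ok])
  m <- sum(truth)
  n <- sum(!truth)
  if (m == 0 || n == 0) {
    stop_ostai("both classes must be present", "ostai_domain_error")
  }
  # one pass over the sorted unique scores: at threshold t the positives are
  # the scores strictly below t, so the rates are shifted cumulative counts
  u <- sort(unique(score))
  idx <- match(score, u)
  case_counts <- tabulate(idx[truth], nbins = length(u))
  ctrl_counts <- tabulate(idx[!truth], nbins = length(u))
  points <- tibble(
    threshold = c(-Inf, u, Inf),
    fpr = c(0, 0, cumsum(ctrl_counts)) / n,
    tpr = c(0, 0, cumsum(case_counts)) / m
  )
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  risk <- -score
  if (ci == "delong") {
    pl <- delong_placements(risk, truth)
    se <- sqrt(var(pl$v10) / pl$m + var(pl$v01) / pl$n)
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    se <- sqrt((auc * (1 - auc) + (m - 1) * (q1 - auc^2) +
                  (n - 1) * (q2 - auc^2)) / (m * n))
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(points = points, auc = auc, se = se,
         ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
         ci_method = ci, conf_level = conf_level,
         n_pos = m, n_neg = n, score = score, truth = truth),
    class = "ostai_roc"
  )
}

#' @export
print.ostai_roc <- function(x, ...) {
  cat(sprintf("<ostai_roc> AUC %.3f (%d%% CI %.3f-%.3f, %s), %d cases / %d controls\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$ci_method, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_curve
#' @param x an `ostai_roc`.
#' @param ... unused.
#' @export
tidy.ostai_roc <- function(x, ...) x$points

#' @rdname roc_curve
#' @export
glance.ostai_roc <- function(x, ...) {
  tibble(auc = x$auc, se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
         ci_method = x$ci_method, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Prevalence of osteoporosis by OSTAi risk category
#'
#' @param data cohort tibble; `ostai_category` and `osteoporotic` are
#'   computed when absent.
#' @param rounding passed to [ostai_score()] when scores must be computed.
#' @return A tibble with one row per risk category: `category`, `cases`,
#'   `total`, `proportion`, `percent`. Category totals sum to the number of
#'   scored participants.
#' @export
category_prevalence <- function(data, rounding = "nearest") {
  if (nrow(data) == 0) stop_ostai("empty cohort", "ostai_domain_error")
  if (!"ostai_category" %in% names(data)) data <- ostai_score(data, rounding)
  if (!"osteoporotic" %in% names(data)) data <- classify_osteoporosis(data)
  out <- purrr::map_dfr(levels(data$ostai_category), function(lv) {
    in_cat <- data$ostai_category == lv
    tibble(category = lv, cases = sum(in_cat & data$osteoporotic, na.rm = TRUE),
           total = sum(in_cat, na.rm = TRUE))
  })
  out$proportion <- ifelse(out$total > 0, out$cases / out$total, NA_real_)
  out$percent <- fmt_pct(out$proportion)
  out
}

#' Diagnostic performance of a screening rule on a cohort
#'
#' Evaluates one screening rule -- the OSTAi index at an integer cutoff, or
#' the NOF 2013 referral rule -- against the WHO osteoporosis case
#' definition on a cohort, producing the 2x2 confusion matrix, the four
#' screening metrics, an ROC curve with AUC and confidence interval, the
#' referral burden, and (for OSTAi) osteoporosis prevalence by risk
#' category. For the binary NOF rule the ROC is the two-segment curve
#' through its single operating point and its AUC equals
#' (sensitivity + specificity) / 2.
#'
#' @param data cohort tibble with T-scores; decisions and status are
#'   computed when absent.
#' @param rule `"ostai"` or `"nof2013"`.
#' @param cutoff integer OSTAi cutoff (default -1).
#' @param rounding passed to [ostai_score()].
#' @param ci CI method for [roc_curve()].
#' @return An object of class `diagnostic_report`.
#' @export
diagnostic_report <- function(data, rule = c("ostai", "nof2013"),
                              cutoff = -1, rounding = "nearest",
                              ci = "delong") {
  rule <- match.arg(rule)
  if (!"osteoporotic" %in% names(data)) data <- classify_osteoporosis(data)
  if (rule == "ostai") {
    data <- ostai_decision(data, cutoff, rounding)
    positive <- data$ostai_positive
    score <- data$ostai_value
    categories <- category_prevalence(data, rounding)
  } else {
    if (!"nof2013_positive" %in% names(data)) data <- classify_nof2013(data)
    positive <- data$nof2013_positive
    score <- 1L - as.integer(positive)
    categories <- NULL
  }
  matrix <- confusion_counts(positive, data$osteoporotic)
  structure(
    list(
      rule = rule,
      cutoff = if (rule == "ostai") as.integer(cutoff) else NA_integer_,
      matrix = matrix,
      metrics = diag_metrics(matrix),
      roc = roc_curve(score, data$osteoporotic, ci),
      category_prevalence = categories,
      n = nrow(data),
      prevalence = mean(data$osteoporotic),
      referral = mean(positive),
      ids = if ("id" %in% names(data)) data$id else NULL
    ),
    class = "diagnostic_report"
  )
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("<diagnostic_report> rule %s on %d women (prevalence %.1f%%)\n",
              x$rule, x$n, 100 * x$prevalence))
  cat(sprintf("  tp %d  fp %d  fn %d  tn %d;  referral %.1f%%\n",
              x$matrix$tp, x$matrix$fp, x$matrix$fn, x$matrix$tn,
              100 * x$referral))
  m <- x$metrics
  cat(sprintf("  %s %.1f%% (%d/%d)\n", m$metric, m$percent,
              m$numerator, m$denominator), sep = "")
  cat(sprintf("  AUC %.3f (%.3f-%.3f, %s)\n", x$roc$auc, x$roc$ci_low,
              x$roc$ci_high, x$roc$ci_method))
  invisible(x)
}

#' @rdname diagnostic_report
#' @param x a `diagnostic_report`.
#' @param ... unused.
#' @export
tidy.diagnostic_report <- function(x, ...) x$metrics

#' @rdname diagnostic_report
#' @export
glance.diagnostic_report <- function(x, ...) {
  est <- setNames(x$metrics$estimate, x$metrics$metric)
  tibble(
    rule = x$rule, n = x$n, prevalence = x$prevalence,
    sensitivity = est[["sensitivity"]], specificity = est[["specificity"]],
    ppv = est[["ppv"]], npv = est[["npv"]],
    auc = x$roc$auc, auc_ci_low = x$roc$ci_low, auc_ci_high = x$roc$ci_high,
    referral = x$referral
  )
}

#' Head-to-head comparison of two screening rules
#'
#' Compares two diagnostic reports computed on the identical cohort:
#' side-by-side metrics, the AUC difference with a confidence interval and
#' p-value from the paired DeLong test (using the per-participant scores
#' stored in each report), and the referral burden of each rule.
#'
#' @param report_a,report_b `diagnostic_report` objects for the same
#'   participants in the same order.
#' @param conf_level confidence level for the AUC-difference interval.
#' @return An object of class `rule_comparison`: a list with `side_by_side`
#'   (tibble), `auc_diff`, `ci_low`, `ci_high`, `p_value`.
#' @export
compare_rules <- function(report_a, report_b, conf_level = 0.95) {
  if (!is.null(report_a$ids) && !is.null(report_b$ids)) {
    if (!identical(report_a$ids, report_b$ids)) {
      stop_ostai("reports were not computed on the identical cohort",
                 "ostai_domain_error")
    }
  } else if (report_a$n != report_b$n) {
    stop_ostai("reports differ in cohort size", "ostai_domain_error")
  }
  if (!identical(report_a$roc$truth, report_b$roc$truth)) {
    stop_ostai("reports disagree on case status; cohorts differ",
               "ostai_domain_error")
  }
  pa <- delong_placements(-report_a$roc$score, report_a$roc$truth)
  pb <- delong_placements(-report_b$roc$score, report_b$roc$truth)
  var_a <- var(pa$v10) / pa$m + var(pa$v01) / pa$n
  var_b <- var(pb$v10) / pb$m + var(pb$v01) / pb$n
  cov_ab <- cov(pa$v10, pb$v10) / pa$m + cov(pa$v01, pb$v01) / pa$n
  diff <- report_a$roc$auc - report_b$roc$auc
  se <- sqrt(max(var_a + var_b - 2 * cov_ab, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- if (se == 0) as.numeric(diff == 0) else 2 * pnorm(-abs(diff / se))
  if (se == 0 && diff == 0) p <- 1
  side <- dplyr::bind_rows(glance(report_a), glance(report_b))
  structure(
    list(side_by_side = side, auc_diff = diff, se = se,
         ci_low = diff - z * se, ci_high = diff + z * se, p_value = p),
    class = "rule_comparison"
  )
}

#' @export
print.rule_comparison <- function(x, ...) {
  print(as.data.frame(x$side_by_side), row.names = FALSE)
  cat(sprintf("AUC difference %.3f (%.3f-%.3f), paired DeLong p = %.3g\n",
              x$auc_diff, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' @rdname compare_rules
#' @param x a `rule_comparison`.
#' @param ... unused.
#' @export
tidy.rule_comparison <- function(x, ...) x$side_by_side

#' @rdname compare_rules
#' @export
glance.rule_comparison <- function(x, ...) {
  tibble(auc_diff = x$auc_diff, se = x$se, ci_low = x$ci_low,
         ci_high = x$ci_high, p_value = x$p_value)
}
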