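#' Plot an ROC curve
#'
#' @param object an `ostai_roc` from [roc_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ostai_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("AUC %.3f (%.3f-%.3f, %s)", object$auc,
                      object$ci_low, object$ci_high, object$ci_method)
    ) +
    ggplot2::theme_minimal()
}

#' Plot two screening rules' ROC curves together
#'
#' @param report_a,report_b `diagnostic_report` objects.
#' @return A ggplot overlaying both curves, labelled by rule.
#' @export
plot_roc_comparison <- function(report_a, report_b) {
  df <- dplyr::bind_rows(
    dplyr::mutate(report_a$roc$points, rule = report_a$rule),
    dplyr::mutate(report_b$roc$points, rule = report_b$rule)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$rule)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter of index values against the lowest T-score
#'
#' The classic presentation of an OSTA-style index: one point per woman,
#' the diagnostic threshold as a horizontal line and the category cutpoints
#' as vertical lines.
#'
#' @param data cohort tibble; `ostai_value` and `lowest_t` are computed
#'   when absent.
#' @param cutoffs vertical reference lines (default the published category
#'   boundaries -1 and -4).
#' @param threshold horizontal diagnostic line (default -2.5).
#' @return A ggplot.
#' @export
plot_index_vs_tscore <- function(data, cutoffs = c(-1, -4), threshold = -2.5) {
  if (!"ostai_value" %in% names(data)) data <- ostai_score(data)
  if (!"lowest_t" %in% names(data)) data <- classify_osteoporosis(data)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$ostai_value, y = .data$lowest_t)) +
    ggplot2::geom_jitter(width = 0.25, height = 0, alpha = 0.2, size = 0.5) +
    ggplot2::geom_hline(yintercept = threshold, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = cutoffs, linetype = "dashed") +
    ggplot2::labs(x = "OSTAi index value", y = "Lowest T-score (SD)") +
    ggplot2::theme_minimal()
}

#' Bar chart of osteoporosis prevalence by risk category
#'
#' @param prevalence a tibble from [category_prevalence()].
#' @return A ggplot.
#' @export
plot_category_prevalence <- function(prevalence) {
  prevalence$category <- factor(prevalence$category,
                                levels = c("low", "medium", "high"))
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = .data$category, y = .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$cases,
                                                    .data$total)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "OSTAi risk category", y = "Osteoporosis prevalence") +
    ggplot2::theme_minimal()
}
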