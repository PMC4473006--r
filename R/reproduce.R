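# Cheap stable polynomial hash of a deparsed R object, used to stamp
# outputs with the configuration they came from.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_stamped_tsv <- function(df, path, stamp) {
  writeLines(c(paste0("# ", stamp), readr::format_tsv(df)), path)
}

#' Reproduce the standard report bundle for a cohort
#'
#' Runs the whole pipeline on a cohort and writes the report files that
#' mirror the published presentation: `table2.tsv` (osteoporotic site
#' combinations), `table3.tsv` (univariate screen, multivariable
#' coefficients and integer index weights), `table4.tsv` (2x2 counts and
#' screening metrics for the OSTAi index and the NOF 2013 rule),
#' `categories.tsv` (prevalence by risk category) and `comparison.json`
#' (head-to-head summary). Every file is stamped with the configuration
#' hash and seed.
#'
#' Three input modes are available: an explicit cohort tibble, a synthetic
#' cohort (`synthetic = TRUE`), or `fixtures = TRUE`, which uses the
#' published summary counts and coefficients from [ostai_reference()] as
#' input -- the raw study data are not distributed, but all table-level
#' metrics can be recomputed from those counts.
#'
#' @param data cohort tibble, or `NULL`.
#' @param output_dir directory to write into (created if needed).
#' @param synthetic generate the input cohort with [generate_cohort()].
#' @param fixtures use the published reference counts instead of
#'   participant-level input.
#' @param n,seed,config synthetic-cohort parameters.
#' @param cutoff OSTAi screening cutoff.
#' @param alpha,tol_auc derivation parameters (participant-level modes).
#' @param sd_multiple QC extreme-value rule multiplier.
#' @return Invisibly, a list of the objects written.
#' @export
reproduce_tables <- function(data = NULL, output_dir, synthetic = FALSE,
                             fixtures = FALSE, n = 12175, seed = 1,
                             config = generator_config(), cutoff = -1,
                             alpha = 0.05, tol_auc = 0.01, sd_multiple = 3) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  run_config <- list(mode = if (fixtures) "fixtures" else if (synthetic) "synthetic" else "data",
                     n = n, seed = seed, cutoff = cutoff, alpha = alpha,
                     tol_auc = tol_auc, sd_multiple = sd_multiple,
                     generator = if (synthetic) unclass(config) else NULL)
  stamp <- paste0("ostai run config ", config_hash(run_config), " seed ", seed)
  out <- list()

  if (fixtures) {
    ref <- ostai_reference()
    tab2 <- ref$site_combinations
    tab2 <- dplyr::bind_rows(tab2, tibble(combination = "total", n = sum(tab2$n)))
    tab2$percent <- fmt_pct(tab2$n / sum(ref$site_combinations$n))
    model <- make_index_weights(ref$multivariable[, c("variable", "beta", "se")])
    tab3 <- dplyr::mutate(ref$multivariable, recomputed_weight =
                            unname(model$weights[ref$multivariable$variable]))
    tab4 <- dplyr::bind_rows(lapply(seq_len(nrow(ref$confusion)), function(i) {
      row <- ref$confusion[i, ]
      dplyr::mutate(diag_metrics(row), rule = row$rule, tp = row$tp,
                    fp = row$fp, fn = row$fn, tn = row$tn)
    }))
    cats <- dplyr::mutate(ref$categories,
                          proportion = .data$cases / .data$total,
                          percent = fmt_pct(.data$cases / .data$total))
    comparison <- list(
      config = run_config, config_hash = config_hash(run_config),
      metrics = split(tab4$percent, tab4$rule) |>
        lapply(function(x) setNames(x, unique(tab4$metric))),
      referral = list(
        ostai = (ref$confusion$tp[1] + ref$confusion$fp[1]) / sum(ref$cohort["n"]),
        nof2013 = (ref$confusion$tp[2] + ref$confusion$fp[2]) / sum(ref$cohort["n"])
      ),
      published_auc = as.list(ref$auc)
    )
  } else {
    if (synthetic) data <- generate_cohort(n, seed, config)
    if (is.null(data)) {
      stop_ostai("provide a cohort, or set synthetic = TRUE or fixtures = TRUE",
                 "ostai_domain_error")
    }
    data <- apply_exclusions(data, sd_multiple)
    data <- classify_osteoporosis(data)
    tab2 <- tabulate_site_combinations(data)
    model <- derive_index(data, alpha = alpha, tol_auc = tol_auc)
    screen <- attr(model, "screen")
    fits <- attr(model, "full_fits")
    tab3 <- dplyr::full_join(
      dplyr::rename(screen, uni_beta = "beta", uni_se = "se", uni_p = "p"),
      dplyr::mutate(fits, index_weight = dplyr::coalesce(
        unname(make_index_weights(fits)$weights[fits$variable]), NA_integer_)),
      by = "variable"
    )
    rep_a <- diagnostic_report(data, "ostai", cutoff = cutoff)
    rep_b <- diagnostic_report(data, "nof2013")
    tab4 <- dplyr::bind_rows(
      dplyr::mutate(tidy(rep_a), rule = "ostai", tp = rep_a$matrix$tp,
                    fp = rep_a$matrix$fp, fn = rep_a$matrix$fn, tn = rep_a$matrix$tn),
      dplyr::mutate(tidy(rep_b), rule = "nof2013", tp = rep_b$matrix$tp,
                    fp = rep_b$matrix$fp, fn = rep_b$matrix$fn, tn = rep_b$matrix$tn)
    )
    cats <- category_prevalence(data)
    cmp <- compare_rules(rep_a, rep_b)
    comparison <- list(
      config = run_config, config_hash = config_hash(run_config),
      derived_model = list(variables = model$variables,
                           weights = as.list(model$weights),
                           scale_anchor = model$scale_anchor,
                           cutoff = model$cutoff),
      rules = dplyr::bind_rows(glance(rep_a), glance(rep_b)),
      auc_difference = glance(cmp)
    )
    out$model <- model
  }

  write_stamped_tsv(tab2, file.path(output_dir, "table2.tsv"), stamp)
  write_stamped_tsv(tab3, file.path(output_dir, "table3.tsv"), stamp)
  write_stamped_tsv(tab4, file.path(output_dir, "table4.tsv"), stamp)
  write_stamped_tsv(cats, file.path(output_dir, "categories.tsv"), stamp)
  jsonlite::write_json(comparison, file.path(output_dir, "comparison.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- c(out, list(table2 = tab2, table3 = tab3, table4 = tab4,
                     categories = cats, comparison = comparison))
  invisible(out)
}
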