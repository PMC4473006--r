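#' Cohort CSV schema
#'
#' Column names and types of the participant-level cohort table used across
#' the package: one row per woman, demographics in natural units (years, cm,
#' kg), per-site BMD T-scores in SD units, and the seven FRAX-style clinical
#' risk factors coded 0/1 with `NA` for an unanswered questionnaire item.
#'
#' @return A named character vector mapping column name to type
#'   (`"character"`, `"double"` or `"integer"`).
#' @export
cohort_schema <- function() {
  c(
    id = "character", sex = "character", menopausal = "character",
    age = "double", height = "double", weight = "double",
    menopause_age = "double",
    t_lumbar = "double", t_femoral_neck = "double", t_total_hip = "double",
    previous_fracture = "integer", parent_hip_fracture = "integer",
    current_smoking = "integer", glucocorticoids = "integer",
    rheumatoid_arthritis = "integer", secondary_osteoporosis = "integer",
    alcohol_3plus_units = "integer"
  )
}

#' Read a cohort CSV
#'
#' Reads a participant table in the [cohort_schema()] layout. Missing values
#' are empty fields; risk factors are 0/1. Rows containing malformed
#' numerics are not silently dropped or nulled: they are removed from the
#' returned cohort and collected in a rejects table available via
#' `attr(x, "rejects")`.
#'
#' @param path path to a CSV file with a header.
#' @return A tibble in the cohort schema, with attribute `rejects` (a tibble
#'   with columns `row`, `col`, `expected`, `actual`) listing rejected rows.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_ostai(paste0("file not found: ", path), "ostai_io_error")
  schema <- cohort_schema()
  col_types <- do.call(readr::cols, c(
    lapply(schema, function(tp) switch(tp,
      character = readr::col_character(),
      double = readr::col_double(),
      integer = readr::col_integer()
    )),
    list(.default = readr::col_skip())
  ))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  if (length(header) == 0) stop_ostai("empty cohort file", "ostai_io_error")
  missing_cols <- setdiff(names(schema), header)
  if (length(missing_cols) > 0) {
    stop_ostai(paste0("missing mandatory columns: ",
                      paste(missing_cols, collapse = ", ")), "ostai_io_error")
  }
  extra <- setdiff(header, names(schema))
  if (length(extra) > 0) {
    warn(paste0("ignoring columns not in the cohort schema: ",
                paste(extra, collapse = ", ")))
  }
  data <- suppressWarnings(readr::read_csv(path, col_types = col_types,
                                           na = "", show_col_types = FALSE))
  probs <- readr::problems(data)
  rejects <- tibble(row = integer(), col = character(),
                    expected = character(), actual = character())
  if (nrow(probs) > 0) {
    rejects <- tibble(
      row = probs$row, col = header[probs$col],
      expected = probs$expected, actual = probs$actual
    )
    data <- data[-unique(probs$row), , drop = FALSE]
  }
  if (nrow(data) == 0 && nrow(rejects) == 0) {
    stop_ostai("cohort file contains no data rows", "ostai_io_error")
  }
  data <- as_tibble(data)[, names(schema)]
  attr(data, "rejects") <- rejects
  data
}

#' Write a cohort CSV
#'
#' @param data cohort tibble.
#' @param path output path; missing values are written as empty fields.
#' @return `data`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(data)
}

#' Apply the study exclusion rules to a cohort
#'
#' Performs the single-pass cohort disposition used when a screening index
#' is derived: (1) remove men, (2) remove women not recorded as
#' postmenopausal, (3) remove participants missing any of the three BMD
#' T-scores, then (4) remove participants whose age, height, weight or
#' menopause age deviates from that variable's mean by more than
#' `sd_multiple` standard deviations. The means and SDs for step 4 are
#' computed once, per variable on complete cases, on the sample surviving
#' steps 1-3 (not iteratively), and the comparison is strict: a value at
#' exactly `sd_multiple` SDs is retained. A missing menopause age exempts a
#' participant from that variable's extreme-value rule only.
#'
#' @param data cohort tibble (see [cohort_schema()]).
#' @param sd_multiple positive multiplier for the extreme-value rule
#'   (default 3).
#' @param reference optional tibble with columns `variable`, `mean`, `sd` to
#'   reuse previously computed step-4 reference statistics (e.g. from
#'   `qc_reference()` of an earlier pass), making the operation idempotent.
#' @return The surviving rows, with attributes `qc_log` (tibble `id`,
#'   `step`, `reason`) and `qc_reference` (the step-4 statistics), both also
#'   accessible via [qc_log()] and [qc_reference()].
#' @export
apply_exclusions <- function(data, sd_multiple = 3, reference = NULL) {
  if (nrow(data) == 0) stop_ostai("empty cohort", "ostai_domain_error")
  if (!is.numeric(sd_multiple) || sd_multiple <= 0) {
    stop_ostai("sd_multiple must be a positive number", "ostai_domain_error")
  }
  if (anyDuplicated(data$id)) {
    stop_ostai("participant ids must be unique", "ostai_domain_error")
  }
  log <- list()
  note <- function(ids, step, reason) {
    if (length(ids) > 0) tibble(id = ids, step = step, reason = reason) else NULL
  }

  drop1 <- data$sex != "female"
  drop1[is.na(drop1)] <- TRUE
  log$male <- note(data$id[drop1], 1L, "male")
  data1 <- data[!drop1, , drop = FALSE]

  drop2 <- data1$menopausal != "post"
  drop2[is.na(drop2)] <- TRUE
  log$pre <- note(data1$id[drop2], 2L, "not_postmenopausal")
  data2 <- data1[!drop2, , drop = FALSE]

  drop3 <- !complete.cases(data2[, .t_score_cols])
  log$bmd <- note(data2$id[drop3], 3L, "missing_bmd")
  data3 <- data2[!drop3, , drop = FALSE]

  qc_vars <- c("age", "height", "weight", "menopause_age")
  if (is.null(reference)) {
    reference <- tibble(
      variable = qc_vars,
      mean = vapply(qc_vars, function(v) mean(data3[[v]], na.rm = TRUE), 0),
      sd = vapply(qc_vars, function(v) sd(data3[[v]], na.rm = TRUE), 0)
    )
  }
  extreme <- rep(FALSE, nrow(data3))
  for (i in seq_len(nrow(reference))) {
    v <- reference$variable[i]
    s <- reference$sd[i]
    if (is.na(s) || s <= 0) next  # degenerate spread: rule not applicable
    dev <- abs(data3[[v]] - reference$mean[i])
    extreme <- extreme | (!is.na(dev) & dev > sd_multiple * s)
  }
  log$extreme <- note(data3$id[extreme], 4L, "extreme_value")
  out <- data3[!extreme, , drop = FALSE]

  qc <- dplyr::bind_rows(log)
  if (is.null(qc)) qc <- tibble(id = character(), step = integer(), reason = character())
  if (nrow(out) == 0) {
    stop_ostai("all participants excluded", "ostai_domain_error", qc_log = qc)
  }
  attr(out, "qc_log") <- qc
  attr(out, "qc_reference") <- reference
  out
}

#' @rdname apply_exclusions
#' @param x a cohort returned by [apply_exclusions()].
#' @export
qc_log <- function(x) attr(x, "qc_log")

#' @rdname apply_exclusions
#' @export
qc_reference <- function(x) attr(x, "qc_reference")

#' Classify osteoporosis from per-site T-scores
#'
#' Applies the WHO case definition: a woman is osteoporotic when the T-score
#' at any measured site (lumbar spine, femoral neck or total hip) is less
#' than or equal to -2.5 SD. The lowest available T-score and per-site flags
#' are appended; sites with a missing T-score yield an `NA` flag and do not
#' enter the minimum.
#'
#' @param data cohort tibble with columns `t_lumbar`, `t_femoral_neck`,
#'   `t_total_hip`.
#' @param threshold diagnostic T-score threshold (default -2.5, inclusive).
#' @return `data` with columns `lowest_t`, `osteoporotic`,
#'   `osteo_lumbar_spine`, `osteo_femoral_neck`, `osteo_total_hip` appended.
#' @export
classify_osteoporosis <- function(data, threshold = -2.5) {
  miss <- setdiff(.t_score_cols, names(data))
  if (length(miss) > 0) {
    stop_ostai(paste0("missing T-score columns: ", paste(miss, collapse = ", ")),
               "ostai_domain_error")
  }
  tmat <- as.matrix(data[, .t_score_cols])
  none <- rowSums(!is.na(tmat)) == 0
  if (any(none)) {
    stop_ostai(paste0(sum(none), " row(s) have no T-score at any site"),
               "ostai_domain_error")
  }
  lowest <- apply(tmat, 1, min, na.rm = TRUE)
  data$lowest_t <- as.numeric(lowest)
  data$osteoporotic <- data$lowest_t <= threshold
  data$osteo_lumbar_spine <- data$t_lumbar <= threshold
  data$osteo_femoral_neck <- data$t_femoral_neck <= threshold
  data$osteo_total_hip <- data$t_total_hip <= threshold
  data
}

#' Tabulate osteoporotic site combinations
#'
#' Counts osteoporotic women by the exact subset of sites at which their
#' T-score is at or below the diagnostic threshold: each woman falls in
#' exactly one of the seven non-empty subsets, so the subset counts
#' partition the osteoporotic group.
#'
#' @param data cohort tibble; per-site flags are computed with
#'   [classify_osteoporosis()] if not already present.
#' @param threshold passed to [classify_osteoporosis()] when flags are
#'   absent.
#' @return A tibble with columns `combination`, `n` and `percent`, one row
#'   per non-empty site subset plus a `total` row; `percent` is relative to
#'   the osteoporotic total.
#' @seealso [site_totals()] to recover per-site totals from the subsets.
#' @export
tabulate_site_combinations <- function(data, threshold = -2.5) {
  flags <- c("osteo_lumbar_spine", "osteo_femoral_neck", "osteo_total_hip")
  if (!all(flags %in% names(data))) data <- classify_osteoporosis(data, threshold)
  ls <- data$osteo_lumbar_spine %in% TRUE
  fn <- data$osteo_femoral_neck %in% TRUE
  th <- data$osteo_total_hip %in% TRUE
  combos <- tibble(
    combination = c(
      "lumbar_spine_only", "femoral_neck_only", "total_hip_only",
      "lumbar_spine+femoral_neck", "lumbar_spine+total_hip",
      "femoral_neck+total_hip", "lumbar_spine+femoral_neck+total_hip"
    ),
    n = c(
      sum(ls & !fn & !th), sum(!ls & fn & !th), sum(!ls & !fn & th),
      sum(ls & fn & !th), sum(ls & !fn & th), sum(!ls & fn & th),
      sum(ls & fn & th)
    )
  )
  total <- sum(combos$n)
  out <- dplyr::bind_rows(combos, tibble(combination = "total", n = total))
  out$percent <- if (total > 0) fmt_pct(out$n / total) else 0
  out
}

#' Per-site osteoporosis totals from a site-combination table
#'
#' Sums, for each site, every subset containing that site, recovering the
#' total number of women osteoporotic at that site; also returns the grand
#' total over all subsets.
#'
#' @param combinations a tibble as returned by
#'   [tabulate_site_combinations()] (the `total` row is optional).
#' @return A tibble with columns `site` (`lumbar_spine`, `femoral_neck`,
#'   `total_hip`, `any`) and `n`.
#' @export
site_totals <- function(combinations) {
  stopifnot(all(c("combination", "n") %in% names(combinations)))
  subsets <- combinations[combinations$combination != "total", , drop = FALSE]
  has <- function(site) grepl(site, subsets$combination, fixed = TRUE)
  tibble(
    site = c(.site_names, "any"),
    n = c(
      sum(subsets$n[has("lumbar_spine")]),
      sum(subsets$n[has("femoral_neck")]),
      sum(subsets$n[has("total_hip")]),
      sum(subsets$n)
    )
  )
}
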