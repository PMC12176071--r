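#' Three-step comparison of two processed datasets
#'
#' Runs the full comparison between two research datasets derived from the
#' same raw extract through different ETL rule-sets:
#'
#' 1. **Demographics** on all patients of each dataset.
#' 2. **Paired per-patient indicators** (contacts, regular consultations
#'    and visits, prescriptions, episodes) on the concordant patients,
#'    with paired t tests and confidence intervals of the mean difference
#'    (sign convention: dataset A minus dataset B).
#' 3. **Diagnosis-group indicators** (prevalence, prescriptions and
#'    regular consultations per 1000 patient-years) on all patients, with
#'    a standardized difference per indicator, treating the rates per 1000
#'    as proportions.
#'
#' No multiple-testing correction is applied.
#'
#' @param ds_a,ds_b `processed_dataset` objects for the same analysis
#'   year.
#' @param link A [concordant()] link; computed when omitted.
#' @param specs Diagnosis-group specs, see [default_diagnosis_groups()].
#' @param conf_level Confidence level of the paired-test intervals.
#' @param consult_codes Regular consultation/visit code set.
#' @param denominator Rate denominator for step 3, see
#'   [diagnosis_group_report()].
#' @param sd_threshold Significance threshold on the absolute standardized
#'   difference.
#' @return An object of class `comparison_report` with tibbles `table1`
#'   (demographics), `table2` (paired indicators), `table3`
#'   (diagnosis-group indicators), the population flow, and a `meta` echo
#'   of the inputs.
#' @export
compare_datasets <- function(ds_a, ds_b,
                             link = NULL,
                             specs = default_diagnosis_groups(),
                             conf_level = 0.95,
                             consult_codes = regular_consult_codes(),
                             denominator = c("total_py", "group_py"),
                             sd_threshold = 0.2) {
  denominator <- match.arg(denominator)
  if (!identical(ds_a$meta$analysis_year, ds_b$meta$analysis_year)) {
    abort_invalid("analysis_year", "datasets must share the analysis year")
  }
  if (is.null(link)) {
    link <- concordant(ds_a, ds_b)
  }

  demo_a <- demographics_table(ds_a)
  demo_b <- demographics_table(ds_b)
  table1 <- dplyr::full_join(
    demo_a, demo_b,
    by = "characteristic", suffix = c("_a", "_b")
  )

  table2 <- compare_paired_indicators(link, conf_level, consult_codes)

  table3 <- compare_diagnosis_groups(
    ds_a, ds_b, specs, consult_codes, denominator, sd_threshold
  )

  out <- list(
    table1 = table1,
    table2 = table2,
    table3 = table3,
    flow = list(
      n_a = link$n_a, n_b = link$n_b, n_shared = link$n_shared,
      n_union = link$n_union,
      concordant_fraction = link$concordant_fraction
    ),
    meta = list(
      name_a = ds_a$meta$name, name_b = ds_b$meta$name,
      analysis_year = ds_a$meta$analysis_year,
      conf_level = conf_level, denominator = denominator,
      sd_threshold = sd_threshold,
      multiple_testing = "none"
    )
  )
  class(out) <- "comparison_report"
  out
}

paired_indicator_names <- function() {
  c("contacts", "regular_consults", "prescriptions", "episodes")
}

compare_paired_indicators <- function(link, conf_level, consult_codes) {
  if (link$n_shared == 0) {
    rlang::inform("no concordant patients: paired indicator step skipped")
    return(NULL)
  }
  rows <- lapply(paired_indicator_names(), function(ind) {
    a <- per_patient_indicator(link$ds_a, ind, consult_codes)
    b <- per_patient_indicator(link$ds_b, ind, consult_codes)
    paired <- dplyr::inner_join(
      a[, c("platform_id", "n")], b[, c("platform_id", "n")],
      by = "platform_id", suffix = c("_a", "_b")
    )
    tt <- paired_t_test(paired$n_a, paired$n_b, conf_level)
    tibble::tibble(
      indicator = ind,
      mean_a = tt$mean_a, sd_a = tt$sd_a,
      mean_b = tt$mean_b, sd_b = tt$sd_b,
      mean_diff = tt$mean_diff,
      t_statistic = tt$t_statistic, p_value = tt$p_value,
      ci_low = tt$ci_low, ci_high = tt$ci_high,
      n = tt$n, degenerate = tt$degenerate
    )
  })
  dplyr::bind_rows(rows)
}

compare_diagnosis_groups <- function(ds_a, ds_b, specs, consult_codes,
                                     denominator, sd_threshold) {
  rows <- lapply(specs, function(spec) {
    ga <- diagnosis_group_report(ds_a, spec, consult_codes, denominator)
    gb <- diagnosis_group_report(ds_b, spec, consult_codes, denominator)
    measures <- c("prevalence", "rx_per_1000py", "consults_per_1000py")
    purrr::map_dfr(measures, function(m) {
      va <- ga[[m]]
      vb <- gb[[m]]
      sd_res <- tryCatch(
        standardized_difference(va / 1000, vb / 1000, sd_threshold),
        error = function(e) {
          rlang::warn(sprintf(
            "standardized difference unavailable for %s/%s: %s",
            spec$label, m, conditionMessage(e)
          ))
          list(sd_value = NA_real_, magnitude = NA_character_, significant = NA)
        }
      )
      tibble::tibble(
        label = spec$label, icpc = spec$icpc_code, measure = m,
        n_cases_a = ga$n_cases, n_cases_b = gb$n_cases,
        group_py_a = ga$group_py, group_py_b = gb$group_py,
        value_a = va, value_b = vb,
        sd_value = sd_res$sd_value,
        magnitude = sd_res$magnitude,
        significant = sd_res$significant
      )
    })
  })
  dplyr::bind_rows(rows)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report: %s vs %s, %d>\n",
    x$meta$name_a, x$meta$name_b, x$meta$analysis_year
  ))
  cat(sprintf(
    "  population: %s vs %s patients, %s concordant (%.1f%%)\n",
    format(x$flow$n_a, big.mark = ","), format(x$flow$n_b, big.mark = ","),
    format(x$flow$n_shared, big.mark = ","),
    100 * x$flow$concordant_fraction
  ))
  if (!is.null(x$table2)) {
    cat("  paired indicators (A minus B):\n")
    for (i in seq_len(nrow(x$table2))) {
      r <- x$table2[i, ]
      cat(sprintf(
        "    %-17s %6.2f vs %6.2f  diff %+6.2f  [%6.2f, %6.2f]  p %s\n",
        r$indicator, r$mean_a, r$mean_b, r$mean_diff, r$ci_low, r$ci_high,
        format.pval(r$p_value, digits = 2)
      ))
    }
  }
  cat("  diagnosis groups (standardized differences):\n")
  for (i in seq_len(nrow(x$table3))) {
    r <- x$table3[i, ]
    cat(sprintf(
      "    %-24s %-20s %8.1f vs %8.1f  SD %+0.2f%s\n",
      r$label, r$measure, r$value_a, r$value_b, r$sd_value,
      ifelse(isTRUE(r$significant), " *", "")
    ))
  }
  invisible(x)
}

#' Write a comparison report to a directory
#'
#' Emits `table1.csv`, `table2.csv`, `table3.csv` (rounded the way such
#' tables are printed: rates to 1 decimal, standardized differences to 2)
#' and `report.json` with the unrounded values and the configuration echo.
#'
#' @param report A `comparison_report`.
#' @param directory Output directory.
#' @return `directory`, invisibly.
#' @export
write_report <- function(report, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(
    report$table1 |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric), ~ round(.x, 1))),
    file.path(directory, "table1.csv"),
    na = ""
  )
  if (!is.null(report$table2)) {
    readr::write_csv(
      report$table2 |>
        dplyr::mutate(dplyr::across(
          c("mean_a", "sd_a", "mean_b", "sd_b", "mean_diff", "ci_low", "ci_high"),
          ~ round(.x, 2)
        )),
      file.path(directory, "table2.csv"),
      na = ""
    )
  }
  readr::write_csv(
    report$table3 |>
      dplyr::mutate(
        dplyr::across(c("value_a", "value_b", "group_py_a", "group_py_b"),
          ~ round(.x, 1)
        ),
        sd_value = round(.data$sd_value, 2)
      ),
    file.path(directory, "table3.csv"),
    na = ""
  )
  jsonlite::write_json(
    report_to_list(report),
    file.path(directory, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns", null = "null"
  )
  invisible(directory)
}

report_to_list <- function(report) {
  list(
    table1 = as.list(report$table1),
    table2 = if (!is.null(report$table2)) as.list(report$table2),
    table3 = as.list(report$table3),
    flow = report$flow,
    meta = report$meta
  )
}

#' Read back a comparison report written by [write_report()]
#'
#' Restores the unrounded report from `report.json`; the round trip is
#' lossless for all numeric content.
#'
#' @param directory Directory containing `report.json`.
#' @return A `comparison_report`.
#' @export
read_report <- function(directory) {
  raw <- jsonlite::read_json(
    file.path(directory, "report.json"),
    simplifyVector = TRUE
  )
  out <- list(
    table1 = tibble::as_tibble(raw$table1),
    table2 = if (!is.null(raw$table2)) tibble::as_tibble(raw$table2),
    table3 = tibble::as_tibble(raw$table3),
    flow = raw$flow,
    meta = raw$meta
  )
  class(out) <- "comparison_report"
  out
}
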