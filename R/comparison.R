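# Research-zone statistics: demographics, per-patient indicators, paired
# tests, rates per 1000 patient-years and standardized differences.

#' Total patient-years of a processed dataset
#'
#' Sum over patients of `0.25 * number of registration quarters`; each
#' patient contributes between 0.25 and 1 patient-year.
#'
#' @param ds A `processed_dataset`.
#' @return A number.
#' @export
patient_years_total <- function(ds) {
  sum(ds$patients$patient_years)
}

#' Demographic summary of a processed dataset
#'
#' Patient count, patient-years (total and per patient), patients per
#' practice (mean and SD), and counts with percentages by age band and
#' sex. Percentages are over the total patient count, rounded to one
#' decimal in the `pct` column; raw values are kept in `value`.
#'
#' @param ds A `processed_dataset`.
#' @return A tibble with columns `characteristic`, `value`, `pct`.
#' @export
demographics_table <- function(ds) {
  p <- ds$patients
  n <- nrow(p)
  per_practice <- dplyr::count(p, .data$practice_id)$n
  rows <- list(
    tibble::tibble(
      characteristic = c(
        "patients", "patient_years", "patient_years_per_patient",
        "patients_per_practice_mean", "patients_per_practice_sd"
      ),
      value = c(
        n, sum(p$patient_years),
        if (n > 0) sum(p$patient_years) / n else NA_real_,
        mean(per_practice), stats::sd(per_practice)
      ),
      pct = NA_real_
    )
  )
  for (split in c("age_band", "sex")) {
    lev <- if (split == "age_band") age_band_levels() else c("male", "female")
    cnt <- table(factor(p[[split]], levels = lev))
    rows[[split]] <- tibble::tibble(
      characteristic = paste0(split, ":", lev),
      value = as.numeric(cnt),
      pct = if (n > 0) round(100 * as.numeric(cnt) / n, 1) else NA_real_
    )
  }
  dplyr::bind_rows(rows)
}

#' Per-patient indicator counts
#'
#' One count per patient of the dataset (zero for patients without
#' events):
#' * `contacts` - contact days (at most one per patient-day),
#' * `regular_consults` - distinct patient-days with a claims code in
#'   `code_set`,
#' * `prescriptions` - prescription records,
#' * `episodes` - episodes overlapping the analysis year.
#'
#' @param ds A `processed_dataset`.
#' @param indicator One of `"contacts"`, `"regular_consults"`,
#'   `"prescriptions"`, `"episodes"`.
#' @param code_set Claims codes defining a regular consultation or visit.
#' @return A tibble with `pseudo_id`, `platform_id`, `n`, one row per
#'   patient.
#' @export
per_patient_indicator <- function(ds,
                                  indicator = c(
                                    "contacts", "regular_consults",
                                    "prescriptions", "episodes"
                                  ),
                                  code_set = regular_consult_codes()) {
  indicator <- rlang::arg_match(indicator)
  events <- switch(indicator,
    contacts = ds$contacts,
    regular_consults = ds$claims |>
      dplyr::filter(.data$claims_code %in% code_set) |>
      dplyr::distinct(.data$pseudo_id, .data$date),
    prescriptions = ds$prescriptions,
    episodes = ds$episodes
  )
  counts <- dplyr::count(events, .data$pseudo_id)
  ds$patients[, c("pseudo_id", "platform_id")] |>
    dplyr::left_join(counts, by = "pseudo_id") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Paired samples t test
#'
#' Classical paired t test on `d = x - y` (dataset A minus dataset B) with
#' a two-sided p value and the confidence interval of the mean difference
#' at `conf_level`. Degenerate inputs (fewer than two pairs, or zero
#' variance of the differences) are flagged rather than erroring; with all
#' differences zero the test statistic is 0 and p is 1.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @param conf_level Confidence level of the interval.
#' @return An object of class `paired_test_result` with fields `mean_a`,
#'   `mean_b`, `sd_a`, `sd_b`, `mean_diff`, `t_statistic`, `df`,
#'   `p_value`, `ci_low`, `ci_high`, `n`, `conf_level`, `degenerate`.
#' @export
paired_t_test <- function(x, y, conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n <- length(d)
  base <- list(
    mean_a = mean(x), mean_b = mean(y),
    sd_a = stats::sd(x), sd_b = stats::sd(y),
    mean_diff = mean(d), n = n, conf_level = conf_level,
    sign_convention = "A minus B"
  )
  if (n < 2 || stats::sd(d) == 0) {
    zero <- n >= 2 && mean(d) == 0
    res <- c(base, list(
      t_statistic = if (zero) 0 else NA_real_,
      df = if (n >= 2) n - 1 else NA_real_,
      p_value = if (zero) 1 else NA_real_,
      ci_low = if (n >= 1) mean(d) else NA_real_,
      ci_high = if (n >= 1) mean(d) else NA_real_,
      degenerate = TRUE
    ))
  } else {
    tt <- stats::t.test(x, y, paired = TRUE, conf.level = conf_level)
    res <- c(base, list(
      t_statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value,
      ci_low = tt$conf.int[1],
      ci_high = tt$conf.int[2],
      degenerate = FALSE
    ))
  }
  class(res) <- "paired_test_result"
  res
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "paired t: mean A %.3f, mean B %.3f, diff %.3f (%s), t = %.3f, p = %.3g, %d%% CI [%.3f, %.3f], n = %d%s\n",
    x$mean_a, x$mean_b, x$mean_diff, x$sign_convention,
    x$t_statistic %||% NA, x$p_value, round(100 * x$conf_level),
    x$ci_low, x$ci_high, x$n,
    if (isTRUE(x$degenerate)) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Prevalence per 1000 patient-years
#'
#' `n_cases / patient_years * 1000`, with at most one disease case per
#' patient.
#'
#' @param n_cases Number of distinct patients with the diagnosis.
#' @param patient_years Patient-years of the population (must be > 0).
#' @return The unrounded rate (tables round to one decimal).
#' @export
prevalence_rate <- function(n_cases, patient_years) {
  if (!is.numeric(patient_years) || any(patient_years <= 0)) {
    abort_invalid("patient_years", "must be > 0")
  }
  n_cases / patient_years * 1000
}

#' Events per 1000 patient-years
#'
#' @param n_events Number of events.
#' @param patient_years Denominator patient-years (must be > 0).
#' @return The unrounded rate.
#' @export
rate_per_1000py <- function(n_events, patient_years) {
  if (!is.numeric(patient_years) || any(patient_years <= 0)) {
    abort_invalid("patient_years", "must be > 0")
  }
  n_events / patient_years * 1000
}

#' Standardized difference of two proportions
#'
#' `(p_a - p_b) / sqrt((p_a (1 - p_a) + p_b (1 - p_b)) / 2)`, the
#' dimensionless two-group difference measure, antisymmetric in its
#' arguments. Absolute values of 0.2, 0.5 and 0.8 band the magnitude as
#' small, medium and large; values at or below 0.2 in absolute value are
#' treated as not significant.
#'
#' @param p_a,p_b Proportions in `[0, 1]` (dataset A and dataset B).
#' @param threshold Significance threshold on `|SD|` (default 0.2).
#' @return A list of class `sd_result`: `sd_value`, `magnitude`
#'   (`negligible`/`small`/`medium`/`large`), `significant`. Errors when
#'   both proportions are degenerate (each 0 or 1), which makes the
#'   denominator vanish.
#' @export
standardized_difference <- function(p_a, p_b, threshold = 0.2) {
  if (any(p_a < 0 | p_a > 1, na.rm = TRUE) ||
    any(p_b < 0 | p_b > 1, na.rm = TRUE)) {
    abort_invalid("p_a", "proportions must lie in [0, 1]")
  }
  denom <- sqrt((p_a * (1 - p_a) + p_b * (1 - p_b)) / 2)
  if (any(denom == 0, na.rm = TRUE)) {
    abort_invalid(
      "p_a",
      "standardized difference undefined: both proportions degenerate (0 or 1)"
    )
  }
  sd_value <- (p_a - p_b) / denom
  out <- list(
    sd_value = sd_value,
    magnitude = sd_magnitude(sd_value),
    significant = abs(sd_value) > threshold
  )
  class(out) <- "sd_result"
  out
}

sd_magnitude <- function(sd_value) {
  cut(abs(sd_value),
    breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
    labels = c("negligible", "small", "medium", "large"),
    right = FALSE
  ) |> as.character()
}

#' @export
print.sd_result <- function(x, ...) {
  cat(sprintf(
    "standardized difference %.4f (%s%s)\n",
    x$sd_value, x$magnitude,
    ifelse(x$significant, ", significant", "")
  ))
  invisible(x)
}

#' Diagnosis-group specifications
#'
#' The shipped indicator diagnoses: diabetes mellitus (ICPC T90, ATC
#' prefixes A10A and A10B), urinary tract infection (U71; G03C, J01C,
#' J01D, J01E, J01G, J01M, J01X) and cough (R05; R05C, R05D, R05X, R06A).
#'
#' @return A list of specs, each with `label`, `icpc_code`,
#'   `atc_prefixes`.
#' @export
default_diagnosis_groups <- function() {
  list(
    list(
      label = "diabetes_mellitus", icpc_code = "T90",
      atc_prefixes = c("A10A", "A10B")
    ),
    list(
      label = "urinary_tract_infection", icpc_code = "U71",
      atc_prefixes = c("G03C", "J01C", "J01D", "J01E", "J01G", "J01M", "J01X")
    ),
    list(
      label = "cough", icpc_code = "R05",
      atc_prefixes = c("R05C", "R05D", "R05X", "R06A")
    )
  )
}

atc_matches_prefixes <- function(atc, prefixes) {
  hit <- rep(FALSE, length(atc))
  for (p in prefixes) {
    hit <- hit | startsWith(atc, p)
  }
  hit
}

#' Health-service-use indicators for one diagnosis group
#'
#' A disease case is a patient with at least one journal record of the
#' group's ICPC code in the analysis year (at most one case per patient).
#' Reports the case count, the cases' patient-years, prevalence per 1000
#' patient-years of the whole population, and the cases' prescriptions
#' (ATC prefix match) and regular consultations/visits per 1000
#' patient-years.
#'
#' @param ds A `processed_dataset`.
#' @param spec A group spec (`label`, `icpc_code`, `atc_prefixes`), see
#'   [default_diagnosis_groups()].
#' @param consult_codes Regular consultation/visit code set.
#' @param denominator Patient-year denominator for the prescription and
#'   consultation rates: `"total_py"` (whole population, default) or
#'   `"group_py"` (the cases' own patient-years). Prevalence always uses
#'   the population denominator.
#' @return A one-row tibble with `label`, `icpc`, `n_cases`, `group_py`,
#'   `py_per_patient`, `prevalence`, `rx_per_1000py`,
#'   `consults_per_1000py`.
#' @export
diagnosis_group_report <- function(ds, spec,
                                   consult_codes = regular_consult_codes(),
                                   denominator = c("total_py", "group_py")) {
  denominator <- match.arg(denominator)
  case_ids <- unique(ds$journal$pseudo_id[ds$journal$icpc == spec$icpc_code])
  n_cases <- length(case_ids)
  group_py <- sum(ds$patients$patient_years[
    ds$patients$pseudo_id %in% case_ids
  ])
  total_py <- patient_years_total(ds)

  rx <- ds$prescriptions[ds$prescriptions$pseudo_id %in% case_ids, ]
  n_rx <- sum(atc_matches_prefixes(rx$atc, spec$atc_prefixes))
  consults <- ds$claims[
    ds$claims$pseudo_id %in% case_ids &
      ds$claims$claims_code %in% consult_codes,
  ] |>
    dplyr::distinct(.data$pseudo_id, .data$date)
  n_consults <- nrow(consults)

  denom <- if (denominator == "group_py") group_py else total_py
  tibble::tibble(
    label = spec$label,
    icpc = spec$icpc_code,
    n_cases = n_cases,
    group_py = group_py,
    py_per_patient = if (n_cases > 0) group_py / n_cases else NA_real_,
    prevalence = if (total_py > 0) prevalence_rate(n_cases, total_py) else NA_real_,
    rx_per_1000py = if (denom > 0) rate_per_1000py(n_rx, denom) else NA_real_,
    consults_per_1000py = if (denom > 0) {
      rate_per_1000py(n_consults, denom)
    } else {
      NA_real_
    }
  )
}
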