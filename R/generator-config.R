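#' Default annual ICPC prevalence table for the generator
#'
#' One row per simulated diagnosis code: the probability that an enrolled
#' patient has the condition coded in a given year (scaled by the fraction
#' of the year the patient is enrolled), whether the condition is chronic
#' (a chronic case persists from its onset year onward), and the mean
#' number of additional coded contacts per case-year beyond the guaranteed
#' first one.
#'
#' Diabetes mellitus (T90), urinary tract infection (U71) and cough (R05)
#' are the indicator diagnoses tracked by the comparison step; hypertension
#' (K86) and low back pain (L03) add realistic chronic and acute background
#' morbidity.
#'
#' @return A tibble with columns `icpc`, `annual_prob`, `chronic`,
#'   `extra_contacts`.
#' @export
default_icpc_prevalence <- function() {
  tibble::tribble(
    ~icpc, ~annual_prob, ~chronic, ~extra_contacts,
    "T90", 0.065, TRUE,  1.2,
    "K86", 0.120, TRUE,  1.0,
    "U71", 0.065, FALSE, 0.8,
    "R05", 0.055, FALSE, 0.8,
    "L03", 0.080, FALSE, 0.6
  )
}

#' Default prescribing rules per simulated diagnosis
#'
#' For each diagnosis code, the ATC codes prescribed to its cases and the
#' expected number of prescription records per case-year. The indicator
#' diagnoses draw from the ATC groups conventionally used for them
#' (A10A/A10B antidiabetics, J01/G03C anti-infectives, R05C/R05D/R06A
#' cough and antihistamine preparations); background codes deliberately
#' avoid those prefixes.
#'
#' @return A tibble with columns `icpc`, `atc`, `per_year`.
#' @export
default_atc_prescribing <- function() {
  tibble::tribble(
    ~icpc, ~atc, ~per_year,
    "T90", "A10BA02", 6.0,
    "T90", "A10AB05", 1.5,
    "K86", "C09AA02", 5.0,
    "K86", "C07AB02", 3.0,
    "U71", "J01CA04", 0.9,
    "U71", "J01XE01", 0.5,
    "U71", "G03CA03", 0.1,
    "R05", "R05CB01", 0.5,
    "R05", "R05DA04", 0.3,
    "R05", "R06AE07", 0.2,
    "L03", "M01AE01", 0.8
  )
}

#' Default catalog of loose (episode-free) journal diagnosis codes
#'
#' Symptom and minor-morbidity ICPC codes attached to routine contact days
#' that the GP codes in the journal without opening a formal episode of
#' care. Codes are disjoint from the indicator diagnoses so configured
#' prevalences stay interpretable.
#'
#' @return A tibble with columns `icpc`, `weight`.
#' @export
default_background_icpc <- function() {
  tibble::tribble(
    ~icpc, ~weight,
    "A04", 0.10,
    "D06", 0.09,
    "H81", 0.06,
    "K01", 0.07,
    "L01", 0.10,
    "N01", 0.11,
    "P76", 0.08,
    "R74", 0.15,
    "S88", 0.13,
    "F70", 0.11
  )
}

#' Default catalog of background ATC codes
#'
#' Medication codes for prescriptions not tied to a simulated diagnosis
#' (statins, antacids, analgesics, ...). Disjoint from the indicator ATC
#' prefix groups.
#'
#' @return A tibble with columns `atc`, `weight`.
#' @export
default_background_atc <- function() {
  tibble::tribble(
    ~atc, ~weight,
    "C10AA05", 0.14,
    "A02BC02", 0.14,
    "N02BE01", 0.18,
    "R03AC02", 0.10,
    "C07AB07", 0.08,
    "B01AC06", 0.12,
    "N05BA04", 0.06,
    "D07AC01", 0.08,
    "H03AA01", 0.05,
    "S01AA01", 0.05
  )
}

#' Default insurance-claims code catalog
#'
#' Five-digit claims codes sampled for contact days, with weights. Includes
#' the five regular consultation and visit codes (12001, 12002, 12003,
#' 12010, 12011) at roughly half the total weight, plus telephone/e-mail
#' contacts, procedures, lab work and practice-support contacts.
#'
#' @return A tibble with columns `code`, `weight`.
#' @export
default_claims_catalog <- function() {
  tibble::tribble(
    ~code, ~weight,
    "12010", 0.06,
    "12011", 0.28,
    "12001", 0.12,
    "12002", 0.03,
    "12003", 0.02,
    "12004", 0.15,
    "12024", 0.04,
    "13012", 0.12,
    "13034", 0.10,
    "12111", 0.08
  )
}

#' Configuration for the synthetic raw-EHR generator
#'
#' Defines the study conditions the generator emulates: eight practices of
#' roughly 5,500-6,000 enrolled patients each, the 2017-2019 event window
#' with 2019 as analysis year, population age/sex structure, contact and
#' prescribing rates, diagnosis prevalences, and the recording
#' imperfections (missing social security numbers, capitation gaps,
#' near-duplicate prescription records) that make the two ETL rule-sets
#' diverge.
#'
#' @param n_practices Number of general practices.
#' @param patients_per_practice_mean,patients_per_practice_sd Normal
#'   parameters for the enrolled-patient count per practice.
#' @param age_band_weights Probabilities of the four age bands 0-4, 5-17,
#'   18-64, 65+ (must sum to 1).
#' @param female_fraction Probability that a patient is female.
#' @param window_start,window_end Calendar bounds of the event window; must
#'   cover the analysis year and at least the two prior years.
#' @param analysis_year Year the research datasets describe.
#' @param ssn_missing_prob Probability that a patient's social security
#'   number is absent from the EHR.
#' @param pc3_pool Number of distinct 3-digit postal-code prefixes in the
#'   population (at most 900).
#' @param mid_year_enrollment_prob Probability that a patient enrolls
#'   during the window rather than before it.
#' @param disenrollment_prob Probability that a patient disenrolls during
#'   the window.
#' @param capitation_gap_prob Per-quarter probability that an otherwise due
#'   capitation fee record is missing.
#' @param contact_rate Mean number of GP contact days per patient-year.
#' @param icpc_prevalence Diagnosis prevalence table, see
#'   [default_icpc_prevalence()].
#' @param atc_prescribing Prescribing rules per diagnosis, see
#'   [default_atc_prescribing()].
#' @param background_icpc Loose journal-code catalog, see
#'   [default_background_icpc()].
#' @param journal_icpc_prob Probability that a routine contact day carries
#'   a loose ICPC-coded journal line.
#' @param episode_record_prob Probability that such a journal line also has
#'   a recorded episode of care.
#' @param episode_open_prob Probability that a recorded non-chronic episode
#'   is left without an end date.
#' @param background_rx_rate Mean background prescriptions per patient-year.
#' @param background_atc Background medication catalog, see
#'   [default_background_atc()].
#' @param pharmacy_source_fraction Probability that a prescription record
#'   originates from pharmacy feedback rather than the GP.
#' @param near_duplicate_prob Probability that a prescription is re-recorded
#'   by the other source within 8 days (GP + pharmacy double record).
#' @param repeat_burst_prob Probability that a GP prescription is followed
#'   by a same-source repeat of the same ATC within 3-8 days.
#' @param extra_claim_prob Probability of a second claims code on a contact
#'   day.
#' @param claims_code_catalog Claims-code catalog, see
#'   [default_claims_catalog()]; must contain the five regular
#'   consultation/visit codes.
#' @param seed Integer seed; [generate_extract()] is deterministic given
#'   the configuration and seed.
#'
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_practices = 8L,
                             patients_per_practice_mean = 5750L,
                             patients_per_practice_sd = 1300L,
                             age_band_weights = c(
                               "0-4" = 0.047, "5-17" = 0.155,
                               "18-64" = 0.579, "65+" = 0.219
                             ),
                             female_fraction = 0.506,
                             window_start = as.Date("2017-01-01"),
                             window_end = as.Date("2019-12-31"),
                             analysis_year = 2019L,
                             ssn_missing_prob = 0.07,
                             pc3_pool = 800L,
                             mid_year_enrollment_prob = 0.06,
                             disenrollment_prob = 0.04,
                             capitation_gap_prob = 0.01,
                             contact_rate = 8.6,
                             icpc_prevalence = default_icpc_prevalence(),
                             atc_prescribing = default_atc_prescribing(),
                             background_icpc = default_background_icpc(),
                             journal_icpc_prob = 0.45,
                             episode_record_prob = 0.25,
                             episode_open_prob = 0.15,
                             background_rx_rate = 4.5,
                             background_atc = default_background_atc(),
                             pharmacy_source_fraction = 0.15,
                             near_duplicate_prob = 0.5,
                             repeat_burst_prob = 0.15,
                             extra_claim_prob = 0.2,
                             claims_code_catalog = default_claims_catalog(),
                             seed = 20190101L) {
  cfg <- list(
    n_practices = as.integer(n_practices),
    patients_per_practice_mean = patients_per_practice_mean,
    patients_per_practice_sd = patients_per_practice_sd,
    age_band_weights = age_band_weights,
    female_fraction = female_fraction,
    window_start = as.Date(window_start),
    window_end = as.Date(window_end),
    analysis_year = as.integer(analysis_year),
    ssn_missing_prob = ssn_missing_prob,
    pc3_pool = as.integer(pc3_pool),
    mid_year_enrollment_prob = mid_year_enrollment_prob,
    disenrollment_prob = disenrollment_prob,
    capitation_gap_prob = capitation_gap_prob,
    contact_rate = contact_rate,
    icpc_prevalence = tibble::as_tibble(icpc_prevalence),
    atc_prescribing = tibble::as_tibble(atc_prescribing),
    background_icpc = tibble::as_tibble(background_icpc),
    journal_icpc_prob = journal_icpc_prob,
    episode_record_prob = episode_record_prob,
    episode_open_prob = episode_open_prob,
    background_rx_rate = background_rx_rate,
    background_atc = tibble::as_tibble(background_atc),
    pharmacy_source_fraction = pharmacy_source_fraction,
    near_duplicate_prob = near_duplicate_prob,
    repeat_burst_prob = repeat_burst_prob,
    extra_claim_prob = extra_claim_prob,
    claims_code_catalog = tibble::as_tibble(claims_code_catalog),
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks all invariants of [generator_config()]; errors name the offending
#' field.
#'
#' @param config A `generator_config` object.
#' @return The configuration, invisibly, if valid.
#' @export
validate_generator_config <- function(config) {
  check_count(config$n_practices, "n_practices", min = 1L)
  if (!is.numeric(config$patients_per_practice_mean) ||
    config$patients_per_practice_mean < 1) {
    abort_invalid("patients_per_practice_mean", "must be a positive number")
  }
  if (!is.numeric(config$patients_per_practice_sd) ||
    config$patients_per_practice_sd < 0) {
    abort_invalid("patients_per_practice_sd", "must be non-negative")
  }
  w <- config$age_band_weights
  if (length(w) != 4L || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    abort_invalid(
      "age_band_weights",
      "must be 4 non-negative weights summing to 1 (within 1e-9)"
    )
  }
  for (f in c(
    "female_fraction", "ssn_missing_prob", "mid_year_enrollment_prob",
    "disenrollment_prob", "capitation_gap_prob", "journal_icpc_prob",
    "episode_record_prob", "episode_open_prob", "pharmacy_source_fraction",
    "near_duplicate_prob", "repeat_burst_prob", "extra_claim_prob"
  )) {
    check_prob(config[[f]], f)
  }
  if (!inherits(config$window_start, "Date") ||
    !inherits(config$window_end, "Date") ||
    config$window_start > config$window_end) {
    abort_invalid("window_start", "window_start/window_end must be ordered dates")
  }
  ay <- config$analysis_year
  if (year_of(config$window_start) > ay - 2L || year_of(config$window_end) < ay) {
    abort_invalid(
      "analysis_year",
      "window must cover the analysis year and at least 2 prior years"
    )
  }
  check_count(config$pc3_pool, "pc3_pool", min = 1L)
  if (config$pc3_pool > 900L) {
    abort_invalid("pc3_pool", "at most 900 distinct 3-digit prefixes (100-999)")
  }
  if (!is.numeric(config$contact_rate) || config$contact_rate < 0 ||
    config$contact_rate > 365) {
    abort_invalid("contact_rate", "must be in [0, 365] contact days per year")
  }
  if (!is.numeric(config$background_rx_rate) || config$background_rx_rate < 0) {
    abort_invalid("background_rx_rate", "must be non-negative")
  }
  prev <- config$icpc_prevalence
  if (!all(c("icpc", "annual_prob", "chronic", "extra_contacts") %in% names(prev))) {
    abort_invalid(
      "icpc_prevalence",
      "needs columns icpc, annual_prob, chronic, extra_contacts"
    )
  }
  if (any(prev$annual_prob < 0 | prev$annual_prob > 1)) {
    abort_invalid("icpc_prevalence", "annual_prob values must be in [0, 1]")
  }
  if (anyDuplicated(prev$icpc)) {
    abort_invalid("icpc_prevalence", "icpc codes must be unique")
  }
  if (!all(c("icpc", "atc", "per_year") %in% names(config$atc_prescribing))) {
    abort_invalid("atc_prescribing", "needs columns icpc, atc, per_year")
  }
  cat <- config$claims_code_catalog
  if (!all(c("code", "weight") %in% names(cat))) {
    abort_invalid("claims_code_catalog", "needs columns code, weight")
  }
  missing_regular <- setdiff(regular_consult_codes(), cat$code)
  if (length(missing_regular) > 0) {
    abort_invalid(
      "claims_code_catalog",
      paste(
        "must contain the regular consultation/visit codes; missing:",
        paste(missing_regular, collapse = ", ")
      )
    )
  }
  check_count(config$seed, "seed")
  invisible(config)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat(sprintf(
    "  %d practices x ~%s patients; window %s .. %s; analysis year %d\n",
    x$n_practices, format(x$patients_per_practice_mean, big.mark = ","),
    x$window_start, x$window_end, x$analysis_year
  ))
  cat(sprintf(
    "  contact rate %.1f/py; %d diagnosis codes; seed %d\n",
    x$contact_rate, nrow(x$icpc_prevalence), x$seed
  ))
  invisible(x)
}
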