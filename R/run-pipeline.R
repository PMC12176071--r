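#' Run an ETL rule-set over a raw extract
#'
#' Applies, in order: pseudonymization (patients whose pseudonym cannot be
#' formed are dropped; patients sharing a pseudonym are dropped or merged
#' per `collision_policy`), the registration-quarter rule with exclusion of
#' patients registered for no quarter of the analysis year, prescription
#' source filtering and deduplication, insurance-claims filtering, contact
#' derivation, and the configured episode mode. The result is a
#' research-zone dataset.
#'
#' @param extract A `raw_ehr_extract`.
#' @param config A [pipeline_config()].
#' @param analysis_year Defaults to the extract's analysis year.
#'
#' @return An object of class `processed_dataset`: tibbles `patients`
#'   (`pseudo_id`, `platform_id`, `practice_id`, `age_band`, `sex`,
#'   `quarters`, `n_quarters`, `patient_years`), `contacts`, `claims`,
#'   `prescriptions`, `journal` and `episodes` (all keyed by `pseudo_id`
#'   and restricted to the analysis year, episodes by overlap), plus
#'   `meta`.
#' @export
run_pipeline <- function(extract, config,
                         analysis_year = extract$meta$analysis_year) {
  stopifnot(inherits(extract, "raw_ehr_extract"))
  validate_pipeline_config(config)
  ay <- as.integer(analysis_year)
  ystart <- as.Date(sprintf("%d-01-01", ay))
  yend <- as.Date(sprintf("%d-12-31", ay))

  raw_patients <- extract$patients
  pseudo <- pseudonymize(raw_patients, config$pseudonym_scheme, config$salt)
  pat <- raw_patients
  pat$pseudo_id <- pseudo
  pat <- pat[!is.na(pat$pseudo_id), ]

  dup_ids <- unique(pat$pseudo_id[duplicated(pat$pseudo_id)])
  collided <- pat$pseudo_id %in% dup_ids
  if (config$collision_policy == "drop") {
    pat <- pat[!collided, ]
  }

  # Quarter rule per raw patient, then (under "collapse") union by pseudonym.
  if (config$quarter_rule == "from_enrollment_date") {
    flags <- quarter_flags_enrollment(
      pat$enrollment_date, pat$disenrollment_date, ay
    )
  } else {
    cap <- extract$capitation |>
      dplyr::summarise(
        lo = min(.data$year * 4L + .data$quarter - 1L),
        hi = max(.data$year * 4L + .data$quarter - 1L),
        .by = "true_id"
      )
    m <- match(pat$true_id, cap$true_id)
    flags <- matrix(FALSE, nrow = nrow(pat), ncol = 4)
    for (q in 1:4) {
      idx <- ay * 4L + q - 1L
      flags[, q] <- !is.na(m) & cap$lo[m] <= idx & cap$hi[m] >= idx
    }
  }

  qdf <- tibble::as_tibble(flags, .name_repair = ~ paste0("q", 1:4))
  pat <- dplyr::bind_cols(pat, qdf)
  members <- pat # every raw patient contributing events
  if (any(duplicated(pat$pseudo_id))) {
    pat <- pat |>
      dplyr::arrange(.data$pseudo_id, .data$true_id) |>
      dplyr::summarise(
        true_id = dplyr::first(.data$true_id),
        practice_id = dplyr::first(.data$practice_id),
        birth_year = dplyr::first(.data$birth_year),
        sex = dplyr::first(.data$sex),
        dplyr::across(dplyr::all_of(paste0("q", 1:4)), any),
        .by = "pseudo_id"
      )
  }

  n_quarters <- rowSums(pat[, paste0("q", 1:4)])
  combo <- vapply(
    0:15,
    function(code) paste(which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0),
      collapse = ";"
    ),
    character(1)
  )
  pat$quarters <- combo[
    1L + pat$q1 + 2L * pat$q2 + 4L * pat$q3 + 8L * pat$q4
  ]
  pat$n_quarters <- as.integer(n_quarters)
  pat$patient_years <- 0.25 * n_quarters
  pat <- pat[pat$n_quarters > 0L, ]

  # Platform resolution reuses the registry pseudonyms computed above:
  # under the pc3 scheme an ambiguous triple is unattributable.
  platform_map <- tibble::tibble(
    pseudo = pseudo, platform = raw_patients$true_id
  )
  platform_map <- platform_map[!is.na(platform_map$pseudo), ]
  if (config$pseudonym_scheme == "pc3_birthyear_sex") {
    amb <- unique(platform_map$pseudo[duplicated(platform_map$pseudo)])
    platform_map <- platform_map[!platform_map$pseudo %in% amb, ]
  }

  patients <- tibble::tibble(
    pseudo_id = pat$pseudo_id,
    platform_id = platform_map$platform[
      match(pat$pseudo_id, platform_map$pseudo)
    ],
    practice_id = pat$practice_id,
    age_band = age_to_band(ay - pat$birth_year),
    sex = pat$sex,
    quarters = pat$quarters,
    n_quarters = pat$n_quarters,
    patient_years = pat$patient_years
  ) |>
    dplyr::arrange(.data$pseudo_id)

  id_map <- members[
    members$pseudo_id %in% patients$pseudo_id, c("true_id", "pseudo_id")
  ]
  map_events <- function(tb) {
    dplyr::inner_join(tb, id_map, by = "true_id") |>
      dplyr::select(-"true_id") |>
      dplyr::relocate("pseudo_id")
  }

  rx <- map_events(extract$prescriptions)
  if (!config$include_pharmacy_prescriptions) {
    rx <- rx[rx$source == "gp", ]
  }
  if (config$dedup_window_days > 0L) {
    rx <- dedupe_prescriptions(rx, config$dedup_window_days)
  }

  claims_all <- map_events(extract$claims_events)
  claims <- filter_claims(claims_all, config$claims_filter)
  contact_claims <- if (is.null(config$contact_codes_filter)) {
    claims
  } else {
    filter_claims(claims_all, config$contact_codes_filter)
  }

  journal <- map_events(extract$journal_contacts)
  episodes_raw <- map_events(extract$episodes)

  if (config$episode_mode == "construct") {
    journal <- apply_symptom_overrule(journal, extract$episodes)
    episodes <- episodes_construct(
      journal, rx, episodes_raw,
      analysis_year = ay,
      lookback_years = config$lookback_years,
      interval_map = config$contact_free_interval_days,
      interval_default = config$contact_free_interval_default,
      chronic_codes = config$chronic_codes
    )
  } else {
    episodes <- episodes_recorded(episodes_raw, ay)
  }

  in_year <- function(tb) tb[tb$date >= ystart & tb$date <= yend, ]

  ds <- list(
    patients = patients,
    contacts = derive_contacts(in_year(contact_claims)),
    claims = in_year(claims) |>
      dplyr::arrange(.data$pseudo_id, .data$date, .data$claims_code),
    prescriptions = in_year(rx[, c("pseudo_id", "date", "atc")]) |>
      dplyr::arrange(.data$pseudo_id, .data$date, .data$atc),
    journal = in_year(journal[, c("pseudo_id", "date", "icpc")]) |>
      dplyr::arrange(.data$pseudo_id, .data$date, .data$icpc),
    episodes = episodes,
    meta = list(
      name = config$name,
      analysis_year = ay,
      pseudonym_scheme = config$pseudonym_scheme,
      salt = config$salt,
      config = config
    )
  )
  class(ds) <- "processed_dataset"
  validate_processed_dataset(ds)
  ds
}

#' Check the invariants of a research-zone dataset
#'
#' Patient-years are `0.25 * n_quarters` within `{0.25, 0.5, 0.75, 1}`;
#' contacts are unique per patient-day; every event row's `pseudo_id`
#' exists in the patient table.
#'
#' @param ds A `processed_dataset`.
#' @return `ds`, invisibly, if valid.
#' @export
validate_processed_dataset <- function(ds) {
  p <- ds$patients
  if (!all(p$patient_years %in% c(0.25, 0.5, 0.75, 1))) {
    abort_invalid("patient_years", "must lie in {0.25, 0.5, 0.75, 1}")
  }
  if (!isTRUE(all.equal(p$patient_years, 0.25 * p$n_quarters))) {
    abort_invalid("patient_years", "must equal 0.25 * n_quarters")
  }
  if (anyDuplicated(ds$contacts[, c("pseudo_id", "date")])) {
    abort_invalid("contacts", "must be unique on (pseudo_id, date)")
  }
  for (tb in c("contacts", "claims", "prescriptions", "journal", "episodes")) {
    if (!all(ds[[tb]]$pseudo_id %in% p$pseudo_id)) {
      abort_invalid(tb, "contains pseudo_id values absent from patients")
    }
  }
  invisible(ds)
}

#' @export
print.processed_dataset <- function(x, ...) {
  cat(sprintf(
    "<processed_dataset: %s, analysis year %d>\n",
    x$meta$name, x$meta$analysis_year
  ))
  cat(sprintf(
    "  %s patients, %.1f patient-years\n",
    format(nrow(x$patients), big.mark = ","),
    sum(x$patients$patient_years)
  ))
  for (tb in c("contacts", "claims", "prescriptions", "journal", "episodes")) {
    cat(sprintf("  %-14s %s rows\n", tb, format(nrow(x[[tb]]), big.mark = ",")))
  }
  invisible(x)
}

processed_table_names <- function() {
  c("patients", "contacts", "claims", "prescriptions", "journal", "episodes")
}

#' Write / read a processed dataset as CSV tables
#'
#' @param ds A `processed_dataset`.
#' @param directory Output directory.
#' @return The directory (write) or a `processed_dataset` (read).
#' @export
write_processed_dataset <- function(ds, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (tb in processed_table_names()) {
    readr::write_csv(ds[[tb]], file.path(directory, paste0(tb, ".csv")), na = "")
  }
  meta <- ds$meta
  meta$config <- unclass(meta$config)
  meta$config$contact_free_interval_days <-
    as.list(meta$config$contact_free_interval_days)
  jsonlite::write_json(
    meta, file.path(directory, "meta.json"),
    auto_unbox = TRUE, null = "null"
  )
  invisible(directory)
}

#' @rdname write_processed_dataset
#' @export
read_processed_dataset <- function(directory) {
  types <- list(
    patients = readr::cols(
      pseudo_id = readr::col_character(),
      platform_id = readr::col_character(),
      practice_id = readr::col_character(),
      age_band = readr::col_character(),
      sex = readr::col_character(),
      quarters = readr::col_character(),
      n_quarters = readr::col_integer(),
      patient_years = readr::col_double()
    ),
    contacts = readr::cols(
      pseudo_id = readr::col_character(), date = readr::col_date()
    ),
    claims = readr::cols(
      pseudo_id = readr::col_character(), date = readr::col_date(),
      claims_code = readr::col_character(), icpc = readr::col_character()
    ),
    prescriptions = readr::cols(
      pseudo_id = readr::col_character(), date = readr::col_date(),
      atc = readr::col_character()
    ),
    journal = readr::cols(
      pseudo_id = readr::col_character(), date = readr::col_date(),
      icpc = readr::col_character()
    ),
    episodes = readr::cols(
      pseudo_id = readr::col_character(), icpc = readr::col_character(),
      start_date = readr::col_date(), end_date = readr::col_date()
    )
  )
  ds <- list()
  for (tb in processed_table_names()) {
    path <- file.path(directory, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      rlang::abort(
        sprintf("missing table file for \"%s\": %s", tb, path),
        class = "ehretl_format_error"
      )
    }
    ds[[tb]] <- readr::read_csv(path, col_types = types[[tb]],
      na = "", show_col_types = FALSE
    )
  }
  meta <- jsonlite::read_json(file.path(directory, "meta.json"),
    simplifyVector = TRUE
  )
  meta$analysis_year <- as.integer(meta$analysis_year)
  ds$meta <- meta
  class(ds) <- "processed_dataset"
  ds
}
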