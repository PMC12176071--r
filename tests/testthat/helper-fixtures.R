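# Shared fixture builders and independent reference implementations.

small_gen_config <- function(...) {
  generator_config(
    n_practices = 2L,
    patients_per_practice_mean = 400L,
    patients_per_practice_sd = 40L,
    ...
  )
}

mk_patients <- function(n = 1,
                        true_id = sprintf("pt%02d", seq_len(n)),
                        practice_id = "pr01",
                        ssn = paste0("ssn", true_id),
                        postal_code = "1234AB",
                        birth_year = 1980L,
                        sex = "female",
                        enrollment_date = as.Date("2015-06-01"),
                        disenrollment_date = as.Date(NA)) {
  tibble::tibble(
    true_id = true_id, practice_id = practice_id, ssn = ssn,
    postal_code = postal_code, birth_year = as.integer(birth_year),
    sex = sex,
    enrollment_date = as.Date(enrollment_date),
    disenrollment_date = as.Date(disenrollment_date)
  )
}

empty_tables <- function() {
  list(
    journal_contacts = tibble::tibble(
      true_id = character(), date = as.Date(character()),
      icpc = character(), episode_key = character()
    ),
    claims_events = tibble::tibble(
      true_id = character(), date = as.Date(character()),
      claims_code = character(), icpc = character()
    ),
    episodes = tibble::tibble(
      episode_key = character(), true_id = character(), icpc = character(),
      start_date = as.Date(character()), end_date = as.Date(character()),
      chronic = logical()
    ),
    prescriptions = tibble::tibble(
      true_id = character(), date = as.Date(character()),
      atc = character(), source = character(), icpc_indication = character()
    ),
    capitation = tibble::tibble(
      true_id = character(), year = integer(), quarter = integer()
    )
  )
}

# Hand-assembled raw extract; full-quarter capitation is derived from the
# enrollment spans unless given explicitly.
mk_extract <- function(patients = mk_patients(),
                       journal_contacts = NULL,
                       claims_events = NULL,
                       episodes = NULL,
                       prescriptions = NULL,
                       capitation = NULL,
                       analysis_year = 2019L) {
  tabs <- empty_tables()
  ex <- list(
    patients = patients,
    journal_contacts = journal_contacts %||% tabs$journal_contacts,
    claims_events = claims_events %||% tabs$claims_events,
    episodes = episodes %||% tabs$episodes,
    prescriptions = prescriptions %||% tabs$prescriptions,
    capitation = capitation %||% full_capitation(patients, 2017:2019)
  )
  ex$meta <- list(
    analysis_year = as.integer(analysis_year),
    window_start = as.Date(sprintf("%d-01-01", analysis_year - 2L)),
    window_end = as.Date(sprintf("%d-12-31", analysis_year)),
    seed = 0L,
    row_counts = lapply(
      ex[c(
        "patients", "journal_contacts", "claims_events", "episodes",
        "prescriptions", "capitation"
      )], nrow
    )
  )
  class(ex) <- "raw_ehr_extract"
  ex
}

full_capitation <- function(patients, years) {
  rows <- list()
  for (i in seq_len(nrow(patients))) {
    for (y in years) {
      for (q in 1:4) {
        qs <- as.Date(sprintf("%d-%02d-01", y, (q - 1) * 3 + 1))
        qe <- seq(qs, by = "3 months", length.out = 2)[2] - 1
        dis <- patients$disenrollment_date[i]
        if (patients$enrollment_date[i] <= qs && (is.na(dis) || dis >= qe)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            true_id = patients$true_id[i], year = y, quarter = q
          )
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(empty_tables()$capitation)
  }
  dplyr::bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- independent reference implementations (oracles) ------------------

# Sequential scan dedup: keep a record iff more than `w` days after the
# last kept record of its (id, atc) group.
ref_dedupe_dates <- function(dates, w) {
  dates <- sort(dates)
  kept <- numeric(0)
  last <- -Inf
  for (d in as.numeric(dates)) {
    if (d - last > w) {
      kept <- c(kept, d)
      last <- d
    }
  }
  as.Date(kept)
}

# Brute-force episode segmentation: enumerate every contiguous partition
# of the sorted encounter dates and keep the unique one whose
# within-segment gaps are <= L and whose between-segment gaps are > L.
ref_segment_episodes <- function(dates, L) {
  dates <- sort(unique(dates))
  k <- length(dates)
  if (k == 0) {
    return(NULL)
  }
  if (k == 1) {
    return(list(dates))
  }
  valid <- list()
  for (mask in 0:(2^(k - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(k - 2))) > 0)
    bounds <- c(0, cuts, k)
    segs <- lapply(seq_len(length(bounds) - 1), function(j) {
      dates[(bounds[j] + 1):bounds[j + 1]]
    })
    ok <- TRUE
    for (j in seq_along(segs)) {
      s <- segs[[j]]
      if (length(s) > 1 && any(diff(as.numeric(s)) > L)) ok <- FALSE
      if (j > 1) {
        gap <- as.numeric(s[1]) - as.numeric(utils::tail(segs[[j - 1]], 1))
        if (gap <= L) ok <- FALSE
      }
    }
    if (ok) valid[[length(valid) + 1]] <- segs
  }
  stopifnot(length(valid) == 1)
  valid[[1]]
}

mk_processed <- function(patients,
                         contacts = NULL, claims = NULL,
                         prescriptions = NULL, journal = NULL,
                         episodes = NULL,
                         analysis_year = 2019L, name = "manual") {
  ds <- list(
    patients = patients,
    contacts = contacts %||% tibble::tibble(
      pseudo_id = character(), date = as.Date(character())
    ),
    claims = claims %||% tibble::tibble(
      pseudo_id = character(), date = as.Date(character()),
      claims_code = character(), icpc = character()
    ),
    prescriptions = prescriptions %||% tibble::tibble(
      pseudo_id = character(), date = as.Date(character()), atc = character()
    ),
    journal = journal %||% tibble::tibble(
      pseudo_id = character(), date = as.Date(character()), icpc = character()
    ),
    episodes = episodes %||% tibble::tibble(
      pseudo_id = character(), icpc = character(),
      start_date = as.Date(character()), end_date = as.Date(character())
    ),
    meta = list(name = name, analysis_year = as.integer(analysis_year))
  )
  class(ds) <- "processed_dataset"
  ds
}

mk_ds_patients <- function(n = 1,
                           pseudo_id = sprintf("ps%02d", seq_len(n)),
                           platform_id = sprintf("pt%02d", seq_len(n)),
                           practice_id = "pr01",
                           age_band = "18-64",
                           sex = "female",
                           n_quarters = 4L) {
  tibble::tibble(
    pseudo_id = pseudo_id, platform_id = platform_id,
    practice_id = practice_id, age_band = age_band, sex = sex,
    quarters = vapply(
      n_quarters,
      function(k) paste(seq_len(k), collapse = ";"), character(1)
    ),
    n_quarters = as.integer(n_quarters),
    patient_years = 0.25 * n_quarters
  )
}
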