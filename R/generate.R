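#' Generate a synthetic raw EHR extract
#'
#' Simulates the "care zone" event tables of a group of general practices:
#' an enrolled patient register with enrollment spans, postal codes, birth
#' years, sex and (occasionally missing) social security numbers; quarterly
#' capitation fee records with occasional gaps; ICPC-coded journal contacts
#' and recorded episodes of care; ATC-coded prescription records from GP
#' and pharmacy sources including near-duplicate double records and repeat
#' bursts; and five-digit insurance-claims events. The output is the raw
#' material both ETL rule-sets consume.
#'
#' The generator is deterministic given `(config, seed)`. Diagnosis case
#' probabilities are scaled by each patient's within-year enrollment
#' exposure, so a configured annual prevalence `p` is recovered as
#' approximately `1000 * p` cases per 1000 patient-years after processing.
#' Every case has at least one ICPC-coded journal contact in each active
#' year, and contact days for a case lie inside the patient's enrollment
#' span.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return An object of class `raw_ehr_extract`: a list of tibbles
#'   `patients`, `journal_contacts`, `claims_events`, `episodes`,
#'   `prescriptions`, `capitation`, plus a `meta` list (window, analysis
#'   year, seed, per-table row counts).
#' @export
generate_extract <- function(config, seed = config$seed) {
  validate_generator_config(config)
  seed <- as.integer(seed)
  withr::with_seed(seed, build_extract(config, seed))
}

build_extract <- function(config, seed) {
  ay <- config$analysis_year
  wstart <- config$window_start
  wend <- config$window_end
  years <- seq(year_of(wstart), year_of(wend))

  patients <- simulate_patients(config)
  py <- patient_year_frame(patients, years, wstart, wend)

  disease <- simulate_disease(config, patients, py, ay, wend)
  background <- simulate_background_days(config, py, disease$day_counts)
  journal_contacts <- dplyr::bind_rows(
    disease$journal,
    background$journal
  ) |>
    dplyr::distinct(.data$true_id, .data$date, .data$icpc, .keep_all = TRUE) |>
    dplyr::arrange(.data$true_id, .data$date, .data$icpc)

  episodes <- dplyr::bind_rows(disease$episodes, background$episodes) |>
    dplyr::arrange(.data$true_id, .data$icpc, .data$start_date, .data$episode_key)

  claims_events <- simulate_claims(config, journal_contacts, background$days)
  prescriptions <- simulate_prescriptions(config, disease$case_years, py, wend)
  capitation <- simulate_capitation(config, patients, years, wstart, wend)

  extract <- list(
    patients = patients,
    journal_contacts = journal_contacts,
    claims_events = claims_events,
    episodes = episodes,
    prescriptions = prescriptions,
    capitation = capitation,
    meta = list(
      analysis_year = ay,
      window_start = wstart,
      window_end = wend,
      seed = seed,
      row_counts = list(
        patients = nrow(patients),
        journal_contacts = nrow(journal_contacts),
        claims_events = nrow(claims_events),
        episodes = nrow(episodes),
        prescriptions = nrow(prescriptions),
        capitation = nrow(capitation)
      )
    )
  )
  class(extract) <- "raw_ehr_extract"
  extract
}

simulate_patients <- function(config) {
  n_per <- pmax(1L, round(stats::rnorm(
    config$n_practices,
    config$patients_per_practice_mean,
    config$patients_per_practice_sd
  )))
  n <- sum(n_per)
  practice_id <- rep(sprintf("pr%02d", seq_len(config$n_practices)), n_per)

  band <- sample(age_band_levels(), n, replace = TRUE, prob = config$age_band_weights)
  lo <- c("0-4" = 0L, "5-17" = 5L, "18-64" = 18L, "65+" = 65L)[band]
  hi <- c("0-4" = 4L, "5-17" = 17L, "18-64" = 64L, "65+" = 95L)[band]
  age <- lo + floor(stats::runif(n) * (hi - lo + 1L))
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")

  pc3 <- sprintf("%03d", sample(seq(100L, 100L + config$pc3_pool - 1L), n, replace = TRUE))
  postal_code <- paste0(
    pc3, sample(0:9, n, replace = TRUE),
    sample(LETTERS, n, replace = TRUE), sample(LETTERS, n, replace = TRUE)
  )
  ssn <- sprintf("ssn%09d", sample.int(9e7, n) + 1e7)
  ssn[stats::runif(n) < config$ssn_missing_prob] <- NA_character_

  window_days <- as.integer(config$window_end - config$window_start) + 1L
  mid <- stats::runif(n) < config$mid_year_enrollment_prob
  enrollment_date <- config$window_start - sample.int(3650L, n, replace = TRUE)
  enrollment_date[mid] <- config$window_start +
    floor(stats::runif(sum(mid)) * window_days)

  disenrollment_date <- as.Date(rep(NA, n))
  leaves <- stats::runif(n) < config$disenrollment_prob
  if (any(leaves)) {
    s <- pmax(enrollment_date[leaves], config$window_start)
    span <- as.numeric(config$window_end - s)
    disenrollment_date[leaves] <- s + floor(stats::runif(sum(leaves)) * (span + 1))
  }

  tibble::tibble(
    true_id = sprintf("pt%07d", seq_len(n)),
    practice_id = practice_id,
    ssn = ssn,
    postal_code = postal_code,
    birth_year = config$analysis_year - as.integer(age),
    sex = sex,
    enrollment_date = enrollment_date,
    disenrollment_date = disenrollment_date
  )
}

# One row per (patient, window year) with positive enrolled days.
patient_year_frame <- function(patients, years, wstart, wend) {
  ystarts <- as.Date(sprintf("%d-01-01", years))
  yends <- as.Date(sprintf("%d-12-31", years))
  tidyr::expand_grid(
    patients[, c("true_id", "enrollment_date", "disenrollment_date")],
    year = years
  ) |>
    dplyr::mutate(
      ystart = ystarts[match(.data$year, years)],
      yend = yends[match(.data$year, years)],
      avail_start = pmax(.data$enrollment_date, .data$ystart, wstart),
      avail_end = pmin(
        dplyr::coalesce(.data$disenrollment_date, as.Date("9999-12-31")),
        .data$yend, wend
      ),
      ndays = as.integer(.data$avail_end - .data$avail_start) + 1L,
      exposure = pmax(.data$ndays, 0L) /
        (as.integer(.data$yend - .data$ystart) + 1L)
    ) |>
    dplyr::filter(.data$ndays > 0L) |>
    dplyr::select(
      "true_id", "year", "avail_start", "avail_end", "ndays", "exposure"
    )
}

sample_days <- function(start, ndays, k) {
  # k iid draws per row over each row's available days (with replacement;
  # duplicate (patient, day, code) journal rows are collapsed downstream).
  rep(start, k) + floor(stats::runif(sum(k)) * rep(ndays, k))
}

simulate_disease <- function(config, patients, py, ay, wend) {
  prev <- config$icpc_prevalence
  py_ay <- py[py$year == ay, ]

  case_years <- list()
  journal <- list()
  episodes <- list()

  first_year <- py |>
    dplyr::summarise(first_year = min(.data$year), .by = "true_id")

  chronic <- prev[prev$chronic, ]
  for (i in seq_len(nrow(chronic))) {
    code <- chronic$icpc[i]
    p <- chronic$annual_prob[i]
    extra <- chronic$extra_contacts[i]
    hit <- py_ay[stats::runif(nrow(py_ay)) < p * py_ay$exposure, "true_id"]
    if (nrow(hit) == 0) next
    cases <- hit |>
      dplyr::left_join(first_year, by = "true_id") |>
      dplyr::mutate(
        onset_year = pmax(
          ay - sample(0:2, dplyr::n(), replace = TRUE, prob = c(0.2, 0.3, 0.5)),
          .data$first_year
        ),
        icpc = code,
        episode_key = paste(.data$true_id, code, "chronic", sep = ":")
      )
    cy <- cases |>
      dplyr::inner_join(py, by = "true_id", relationship = "many-to-many") |>
      dplyr::filter(.data$year >= .data$onset_year) |>
      dplyr::mutate(
        start = dplyr::if_else(
          .data$year == .data$onset_year,
          .data$avail_start +
            floor(stats::runif(dplyr::n()) * .data$ndays * 0.5),
          .data$avail_start
        ),
        span = as.integer(.data$avail_end - .data$start) + 1L,
        k = 1L + stats::rpois(dplyr::n(), extra)
      )
    jc <- tibble::tibble(
      true_id = rep(cy$true_id, cy$k),
      date = sample_days(cy$start, cy$span, cy$k),
      icpc = code,
      episode_key = rep(cy$episode_key, cy$k)
    )
    ep <- cy |>
      dplyr::group_by(.data$true_id, .data$episode_key) |>
      dplyr::summarise(onset = min(.data$start), .groups = "drop") |>
      dplyr::transmute(
        episode_key = .data$episode_key,
        true_id = .data$true_id,
        icpc = code,
        start_date = .data$onset,
        end_date = as.Date(NA),
        chronic = TRUE
      )
    case_years[[code]] <- cy |>
      dplyr::select("true_id", "year", "icpc", "avail_start", "avail_end",
        "ndays", "exposure"
      )
    journal[[code]] <- jc
    episodes[[code]] <- ep
  }

  acute <- prev[!prev$chronic, ]
  for (i in seq_len(nrow(acute))) {
    code <- acute$icpc[i]
    p <- acute$annual_prob[i]
    extra <- acute$extra_contacts[i]
    cy <- py[stats::runif(nrow(py)) < p * py$exposure, ] |>
      dplyr::mutate(
        icpc = code,
        episode_key = paste(.data$true_id, code, .data$year, sep = ":"),
        center = .data$avail_start +
          floor(stats::runif(dplyr::n()) * .data$ndays),
        k = 1L + stats::rpois(dplyr::n(), extra)
      )
    if (nrow(cy) == 0) next
    jc <- tibble::tibble(
      true_id = rep(cy$true_id, cy$k),
      date = rep(cy$center, cy$k) +
        round(stats::rnorm(sum(cy$k), 0, 12)),
      icpc = code,
      episode_key = rep(cy$episode_key, cy$k),
      lo = rep(cy$avail_start, cy$k),
      hi = rep(cy$avail_end, cy$k)
    ) |>
      dplyr::mutate(
        date = pmin(pmax(.data$date, .data$lo), .data$hi)
      ) |>
      dplyr::select(-"lo", -"hi")
    ep <- jc |>
      dplyr::group_by(.data$true_id, .data$episode_key) |>
      dplyr::summarise(
        start_date = min(.data$date),
        last = max(.data$date),
        .groups = "drop"
      ) |>
      dplyr::mutate(
        icpc = code,
        end_date = dplyr::if_else(
          stats::runif(dplyr::n()) < config$episode_open_prob,
          as.Date(NA),
          pmin(.data$last + 21L, wend)
        ),
        chronic = FALSE
      ) |>
      dplyr::select(
        "episode_key", "true_id", "icpc", "start_date", "end_date", "chronic"
      )
    case_years[[code]] <- cy |>
      dplyr::select("true_id", "year", "icpc", "avail_start", "avail_end",
        "ndays", "exposure"
      )
    journal[[code]] <- jc
    episodes[[code]] <- ep
  }

  journal <- dplyr::bind_rows(journal)
  if (nrow(journal) == 0) {
    journal <- tibble::tibble(
      true_id = character(), date = as.Date(character()),
      icpc = character(), episode_key = character()
    )
  }
  day_counts <- journal |>
    dplyr::mutate(year = year_of(.data$date)) |>
    dplyr::distinct(.data$true_id, .data$year, .data$date) |>
    dplyr::count(.data$true_id, .data$year, name = "n_disease_days")

  list(
    journal = journal,
    episodes = dplyr::bind_rows(episodes),
    case_years = dplyr::bind_rows(case_years),
    day_counts = day_counts,
    disease_days = journal |>
      dplyr::distinct(.data$true_id, .data$date, .keep_all = TRUE)
  )
}

simulate_background_days <- function(config, py, day_counts) {
  df <- py |>
    dplyr::left_join(day_counts, by = c("true_id", "year")) |>
    dplyr::mutate(
      n_disease_days = dplyr::coalesce(.data$n_disease_days, 0L),
      n_target = stats::rbinom(
        dplyr::n(), .data$ndays, min(config$contact_rate / 365, 1)
      ),
      n_extra = pmax(.data$n_target - .data$n_disease_days, 0L)
    ) |>
    dplyr::filter(.data$n_extra > 0L)

  if (nrow(df) == 0) {
    days <- tibble::tibble(
      true_id = character(), date = as.Date(character())
    )
  } else {
    offsets <- unlist(
      Map(sample.int, df$ndays, df$n_extra),
      use.names = FALSE
    )
    days <- tibble::tibble(
      true_id = rep(df$true_id, df$n_extra),
      date = rep(df$avail_start, df$n_extra) + offsets - 1L
    )
  }

  coded <- days[stats::runif(nrow(days)) < config$journal_icpc_prob, ]
  bg <- config$background_icpc
  coded$icpc <- sample(bg$icpc, nrow(coded), replace = TRUE, prob = bg$weight)
  recorded <- stats::runif(nrow(coded)) < config$episode_record_prob
  coded$episode_key <- NA_character_
  coded$episode_key[recorded] <- paste(
    coded$true_id[recorded], coded$icpc[recorded],
    as.integer(coded$date[recorded]),
    sep = ":"
  )
  rec <- coded[recorded, ]
  episodes <- tibble::tibble(
    episode_key = rec$episode_key,
    true_id = rec$true_id,
    icpc = rec$icpc,
    start_date = rec$date,
    end_date = dplyr::if_else(
      stats::runif(nrow(rec)) < config$episode_open_prob,
      as.Date(NA),
      pmin(rec$date + 21L, config$window_end)
    ),
    chronic = FALSE
  )
  list(journal = coded, episodes = episodes, days = days)
}

simulate_claims <- function(config, journal_contacts, background_days) {
  day_icpc <- journal_contacts |>
    dplyr::distinct(.data$true_id, .data$date, .keep_all = TRUE) |>
    dplyr::select("true_id", "date", "icpc")
  contact_days <- dplyr::bind_rows(
    day_icpc,
    background_days |> dplyr::mutate(icpc = NA_character_)
  ) |>
    dplyr::distinct(.data$true_id, .data$date, .keep_all = TRUE)

  cat <- config$claims_code_catalog
  n <- nrow(contact_days)
  first <- contact_days |>
    dplyr::mutate(
      claims_code = sample(cat$code, n, replace = TRUE, prob = cat$weight)
    )
  second_idx <- stats::runif(n) < config$extra_claim_prob
  second <- contact_days[second_idx, ] |>
    dplyr::mutate(
      claims_code = sample(cat$code, sum(second_idx), replace = TRUE,
        prob = cat$weight
      ),
      icpc = NA_character_
    )
  dplyr::bind_rows(first, second) |>
    dplyr::select("true_id", "date", "claims_code", "icpc") |>
    dplyr::arrange(.data$true_id, .data$date, .data$claims_code)
}

simulate_prescriptions <- function(config, case_years, py, wend) {
  rx <- list()

  if (nrow(case_years) > 0) {
    dz <- case_years |>
      dplyr::inner_join(config$atc_prescribing, by = "icpc",
        relationship = "many-to-many"
      ) |>
      dplyr::mutate(
        n_rx = stats::rpois(dplyr::n(), .data$per_year * .data$exposure)
      ) |>
      dplyr::filter(.data$n_rx > 0L)
    if (nrow(dz) > 0) {
      rx$disease <- tibble::tibble(
        true_id = rep(dz$true_id, dz$n_rx),
        date = sample_days(dz$avail_start, dz$ndays, dz$n_rx),
        atc = rep(dz$atc, dz$n_rx),
        icpc_indication = rep(dz$icpc, dz$n_rx)
      )
    }
  }

  bgp <- py |>
    dplyr::mutate(
      n_rx = stats::rpois(
        dplyr::n(), config$background_rx_rate * .data$exposure
      )
    ) |>
    dplyr::filter(.data$n_rx > 0L)
  if (nrow(bgp) > 0) {
    bga <- config$background_atc
    rx$background <- tibble::tibble(
      true_id = rep(bgp$true_id, bgp$n_rx),
      date = sample_days(bgp$avail_start, bgp$ndays, bgp$n_rx),
      atc = sample(bga$atc, sum(bgp$n_rx), replace = TRUE, prob = bga$weight),
      icpc_indication = NA_character_
    )
  }

  rx <- dplyr::bind_rows(rx)
  if (nrow(rx) == 0) {
    return(tibble::tibble(
      true_id = character(), date = as.Date(character()),
      atc = character(), source = character(),
      icpc_indication = character()
    ))
  }
  n <- nrow(rx)
  rx$source <- rep("gp", n)
  rx$source[stats::runif(n) < config$pharmacy_source_fraction] <- "pharmacy"

  # Cross-source re-record of the same prescription within 8 days.
  dup_idx <- stats::runif(n) < config$near_duplicate_prob
  dups <- rx[dup_idx, ]
  if (nrow(dups) > 0) {
    dups$date <- pmin(dups$date + sample(1:8, nrow(dups), replace = TRUE), wend)
    dups$source <- unname(c(gp = "pharmacy", pharmacy = "gp")[dups$source])
  }

  # Same-source repeat of the same ATC shortly after (dose adjustments,
  # early repeats); kept by a raw count, collapsed by an 8-day dedup rule.
  burst_idx <- rx$source == "gp" &
    stats::runif(n) < config$repeat_burst_prob
  bursts <- rx[burst_idx, ]
  if (nrow(bursts) > 0) {
    bursts$date <- pmin(
      bursts$date + sample(3:8, nrow(bursts), replace = TRUE), wend
    )
  }

  dplyr::bind_rows(rx, dups, bursts) |>
    dplyr::select("true_id", "date", "atc", "source", "icpc_indication") |>
    dplyr::arrange(
      .data$true_id, .data$date, .data$atc, .data$source
    )
}

simulate_capitation <- function(config, patients, years, wstart, wend) {
  grid <- tidyr::expand_grid(year = years, quarter = 1:4) |>
    dplyr::mutate(
      qstart = quarter_start(.data$year, .data$quarter),
      qend = quarter_end(.data$year, .data$quarter)
    ) |>
    dplyr::filter(.data$qstart >= wstart, .data$qend <= wend)

  fees <- tidyr::expand_grid(
    patients[, c("true_id", "enrollment_date", "disenrollment_date")],
    grid
  ) |>
    dplyr::filter(
      .data$enrollment_date <= .data$qstart,
      is.na(.data$disenrollment_date) | .data$disenrollment_date >= .data$qend
    )
  fees <- fees[stats::runif(nrow(fees)) >= config$capitation_gap_prob, ]
  fees |>
    dplyr::select("true_id", "year", "quarter") |>
    dplyr::arrange(.data$true_id, .data$year, .data$quarter)
}

#' @export
print.raw_ehr_extract <- function(x, ...) {
  cat("<raw_ehr_extract>\n")
  cat(sprintf(
    "  window %s .. %s; analysis year %d; seed %d\n",
    x$meta$window_start, x$meta$window_end, x$meta$analysis_year, x$meta$seed
  ))
  for (tb in extract_table_names()) {
    cat(sprintf("  %-17s %s rows\n", tb, format(nrow(x[[tb]]), big.mark = ",")))
  }
  invisible(x)
}

extract_table_names <- function() {
  c(
    "patients", "journal_contacts", "claims_events", "episodes",
    "prescriptions", "capitation"
  )
}
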