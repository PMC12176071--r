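# Database-zone processing stages. Each stage is a pure function; the two
# shipped rule-sets differ only in which stages run and with what options.

# TRUE at the first row of each contiguous (a, b) group.
new_group_flags <- function(a, b) {
  n <- length(a)
  if (n == 0) {
    return(logical(0))
  }
  c(TRUE, a[-1] != a[-n] | b[-1] != b[-n])
}

#' Registration quarters from the enrollment span
#'
#' A quarter of the analysis year counts only if the enrollment span covers
#' it entirely: a patient enrolling after the quarter's first day is
#' registered from the next quarter onward, and a patient disenrolling
#' before the quarter's last day loses that quarter.
#'
#' @param enrollment_date,disenrollment_date Calendar dates; an `NA`
#'   disenrollment means the registration is open-ended.
#' @param analysis_year Year whose quarters are assessed.
#' @return Sorted integer vector of registered quarters (possibly empty).
#' @export
quarters_from_enrollment <- function(enrollment_date,
                                     disenrollment_date = as.Date(NA),
                                     analysis_year) {
  if (!is.na(disenrollment_date) && disenrollment_date < enrollment_date) {
    abort_invalid(
      "disenrollment_date",
      "must not precede enrollment_date"
    )
  }
  flags <- quarter_flags_enrollment(
    enrollment_date, disenrollment_date, analysis_year
  )
  which(flags[1, ])
}

quarter_flags_enrollment <- function(enrollment, disenrollment, analysis_year) {
  n <- length(enrollment)
  flags <- matrix(FALSE, nrow = n, ncol = 4)
  for (q in 1:4) {
    qs <- quarter_start(analysis_year, q)
    qe <- quarter_end(analysis_year, q)
    flags[, q] <- enrollment <= qs &
      (is.na(disenrollment) | disenrollment >= qe)
  }
  flags
}

#' Registration quarters from capitation fee records
#'
#' Quarters covered by capitation fees, with missing quarters between the
#' patient's first and last fee record imputed, intersected with the
#' analysis year. No extrapolation beyond the observed span.
#'
#' @param capitation_quarters A data frame with columns `year` and
#'   `quarter` (the patient's fee records), or an empty data frame.
#' @param analysis_year Year whose quarters are assessed.
#' @return Sorted integer vector of registered quarters (possibly empty).
#' @export
quarters_from_capitation <- function(capitation_quarters, analysis_year) {
  if (is.null(capitation_quarters) || nrow(capitation_quarters) == 0) {
    return(integer(0))
  }
  idx <- capitation_quarters$year * 4L + (capitation_quarters$quarter - 1L)
  lo <- min(idx)
  hi <- max(idx)
  ay_idx <- analysis_year * 4L + 0:3
  which(ay_idx >= lo & ay_idx <= hi)
}

#' Pseudonymize patients
#'
#' Replaces direct identifiers by a deterministic keyed hash: either of the
#' social security number (absent when the number is missing) or of the
#' triple (first three postal-code digits, birth year, sex), which can
#' collide between patients.
#'
#' @param patients A patient table with columns `ssn`, `postal_code`,
#'   `birth_year`, `sex`.
#' @param scheme `"pc3_birthyear_sex"` or `"ssn"`.
#' @param salt Keying string mixed into the hash.
#' @return Character vector of pseudonyms aligned with `patients` rows;
#'   `NA` where the scheme's source field is missing.
#' @export
pseudonymize <- function(patients,
                         scheme = c("pc3_birthyear_sex", "ssn"),
                         salt = "") {
  scheme <- match.arg(scheme)
  key <- if (scheme == "ssn") {
    ifelse(
      is.na(patients$ssn), NA_character_,
      paste("ssn", salt, patients$ssn)
    )
  } else {
    paste(
      "pc3", salt, substr(patients$postal_code, 1, 3),
      patients$birth_year, patients$sex
    )
  }
  keyed_hash(key)
}

#' Filter insurance-claims events by code
#'
#' @param claims A claims table with a `claims_code` column.
#' @param code_filter `"all"` (identity) or an explicit character vector of
#'   codes to retain. An empty explicit filter is allowed but warns.
#' @return The retained rows, original order preserved.
#' @export
filter_claims <- function(claims, code_filter) {
  if (identical(code_filter, "all")) {
    return(claims)
  }
  if (length(code_filter) == 0) {
    rlang::warn("empty claims code filter: all claims rows removed")
    return(claims[0, ])
  }
  claims[claims$claims_code %in% code_filter, ]
}

#' Derive contacts from claims events
#'
#' A contact is a patient-day with at least one claims code: at most one
#' contact per patient per day, whatever the number of codes recorded.
#'
#' @param claims A claims table with columns `pseudo_id` and `date`.
#' @return A contacts table with one row per distinct (`pseudo_id`,
#'   `date`).
#' @export
derive_contacts <- function(claims) {
  dplyr::distinct(claims[, c("pseudo_id", "date")]) |>
    dplyr::arrange(.data$pseudo_id, .data$date)
}

#' Deduplicate prescription records
#'
#' Within each (`pseudo_id`, `atc`) group, records are scanned in ascending
#' date order and a record is dropped when its date is at most
#' `window_days` after the last kept record of the group (the window
#' boundary is inclusive). The greedy scan keeps the first record of a
#' burst and accepts a new record once more than `window_days` have passed
#' since the last kept one; the operation is idempotent. With
#' `window_days = 0` only exact same-day duplicates of the same ATC
#' collapse.
#'
#' @param prescriptions A prescriptions table with columns `pseudo_id`,
#'   `date`, `atc`.
#' @param window_days Non-negative integer window.
#' @return The deduplicated table.
#' @export
dedupe_prescriptions <- function(prescriptions, window_days) {
  check_count(window_days, "window_days")
  n <- nrow(prescriptions)
  if (n == 0) {
    return(prescriptions)
  }
  ord <- order(
    prescriptions$pseudo_id, prescriptions$atc, prescriptions$date,
    method = "radix"
  )
  x <- prescriptions[ord, ]
  grp <- paste(x$pseudo_id, x$atc, sep = "\r")
  gid <- cumsum(c(TRUE, grp[-1] != grp[-n]))
  d <- as.integer(x$date)
  # Vectorized greedy scan: in each round, the earliest still-undecided
  # duplicate of every chain is dropped; converges in at most the length
  # of the longest within-window chain.
  keep <- rep(TRUE, n)
  repeat {
    ki <- which(keep)
    m <- length(ki)
    prev_same <- c(FALSE, gid[ki[-m]] == gid[ki[-1]])
    gap <- c(NA_integer_, d[ki[-1]] - d[ki[-m]])
    cand <- prev_same & !is.na(gap) & gap <= window_days
    drop_now <- cand & !c(FALSE, cand[-m])
    if (!any(drop_now)) break
    keep[ki[drop_now]] <- FALSE
  }
  x[keep, ]
}

#' Recorded episodes of care overlapping the analysis year
#'
#' Pass-through of episodes as recorded in the EHR, restricted to those
#' whose interval (start to end, or open-ended) overlaps the analysis
#' year. No end dates are synthesized.
#'
#' @param episode_records An episode table with columns `pseudo_id`,
#'   `icpc`, `start_date`, `end_date`.
#' @param analysis_year Year of interest.
#' @return Episodes table with columns `pseudo_id`, `icpc`, `start_date`,
#'   `end_date`.
#' @export
episodes_recorded <- function(episode_records, analysis_year) {
  ystart <- as.Date(sprintf("%d-01-01", analysis_year))
  yend <- as.Date(sprintf("%d-12-31", analysis_year))
  episode_records |>
    dplyr::filter(
      .data$start_date <= yend,
      is.na(.data$end_date) | .data$end_date >= ystart
    ) |>
    dplyr::select("pseudo_id", "icpc", "start_date", "end_date") |>
    dplyr::arrange(.data$pseudo_id, .data$icpc, .data$start_date)
}

#' Episode-of-care construct
#'
#' Rebuilds episodes from coded encounters instead of trusting recorded
#' end dates. For each patient and ICPC code, encounter dates are pooled
#' from journal contacts with that code, prescriptions whose indication is
#' that code, and the start dates of recorded episodes, over the analysis
#' year and `lookback_years` prior years. Sorted encounters are split into
#' episodes wherever the gap to the previous encounter exceeds the code's
#' contact-free interval `L`; each episode runs from its first encounter to
#' its last encounter plus `floor(L / 2)` days. Codes in `chronic_codes`
#' instead yield a single never-closing episode from the first encounter.
#' Only episodes overlapping the analysis year are returned.
#'
#' @param journal_contacts Journal table (`pseudo_id`, `date`, `icpc`).
#' @param prescriptions Prescriptions table (`pseudo_id`, `date`,
#'   `icpc_indication`).
#' @param episode_records Recorded episodes (`pseudo_id`, `icpc`,
#'   `start_date`), used only to seed encounter dates.
#' @param analysis_year Year of interest.
#' @param lookback_years Years of history pooled before the analysis year.
#' @param interval_map Named numeric vector of per-code contact-free
#'   intervals in days.
#' @param interval_default Interval for codes absent from the map (noted
#'   once per call).
#' @param chronic_codes Codes producing one open-ended episode.
#' @return Episodes table with columns `pseudo_id`, `icpc`, `start_date`,
#'   `end_date` (`NA` end for chronic codes).
#' @export
episodes_construct <- function(journal_contacts,
                               prescriptions,
                               episode_records = NULL,
                               analysis_year,
                               lookback_years = 2L,
                               interval_map = c(U71 = 28, R05 = 90),
                               interval_default = 90,
                               chronic_codes = c("T90", "K86")) {
  pool_start <- as.Date(sprintf("%d-01-01", analysis_year - lookback_years))
  ystart <- as.Date(sprintf("%d-01-01", analysis_year))
  yend <- as.Date(sprintf("%d-12-31", analysis_year))

  enc <- dplyr::bind_rows(
    journal_contacts[, c("pseudo_id", "date", "icpc")],
    prescriptions |>
      dplyr::filter(!is.na(.data$icpc_indication)) |>
      dplyr::transmute(
        pseudo_id = .data$pseudo_id, date = .data$date,
        icpc = .data$icpc_indication
      ),
    if (!is.null(episode_records) && nrow(episode_records) > 0) {
      episode_records |>
        dplyr::transmute(
          pseudo_id = .data$pseudo_id, date = .data$start_date,
          icpc = .data$icpc
        )
    }
  ) |>
    dplyr::filter(.data$date >= pool_start, .data$date <= yend) |>
    dplyr::distinct(.data$pseudo_id, .data$icpc, .data$date) |>
    dplyr::arrange(.data$pseudo_id, .data$icpc, .data$date)

  if (nrow(enc) == 0) {
    return(tibble::tibble(
      pseudo_id = character(), icpc = character(),
      start_date = as.Date(character()), end_date = as.Date(character())
    ))
  }

  unknown <- setdiff(unique(enc$icpc), c(names(interval_map), chronic_codes))
  if (length(unknown) > 0) {
    rlang::inform(sprintf(
      "episode construct: using default contact-free interval (%g d) for: %s",
      interval_default, paste(sort(unknown), collapse = ", ")
    ))
  }
  iv <- unname(interval_map[enc$icpc])
  iv[is.na(iv)] <- interval_default

  # enc is sorted by (pseudo_id, icpc, date); every (patient, code) group
  # is contiguous, so episode splitting reduces to run-length logic.
  is_chronic <- enc$icpc %in% chronic_codes

  ch <- enc[is_chronic, ]
  chronic_eps <- NULL
  if (nrow(ch) > 0) {
    first <- new_group_flags(ch$pseudo_id, ch$icpc)
    chronic_eps <- tibble::tibble(
      pseudo_id = ch$pseudo_id[first],
      icpc = ch$icpc[first],
      start_date = ch$date[first],
      end_date = as.Date(NA)
    )
  }

  ac <- enc[!is_chronic, ]
  acute_eps <- NULL
  if (nrow(ac) > 0) {
    interval <- iv[!is_chronic]
    na <- nrow(ac)
    first <- new_group_flags(ac$pseudo_id, ac$icpc)
    gap <- c(NA_integer_, as.integer(ac$date[-1] - ac$date[-na]))
    new_ep <- first | (!is.na(gap) & gap > interval)
    starts <- which(new_ep)
    ends <- c(starts[-1] - 1L, na)
    acute_eps <- tibble::tibble(
      pseudo_id = ac$pseudo_id[starts],
      icpc = ac$icpc[starts],
      start_date = ac$date[starts],
      end_date = ac$date[ends] + floor(interval[starts] / 2)
    )
  }

  dplyr::bind_rows(chronic_eps, acute_eps) |>
    dplyr::filter(
      .data$start_date <= yend,
      is.na(.data$end_date) | .data$end_date >= ystart
    ) |>
    dplyr::arrange(.data$pseudo_id, .data$icpc, .data$start_date)
}

#' Overrule symptom codes by their linked episode
#'
#' When a journal contact is recorded under an episode of care carrying a
#' different ICPC code (a symptom filed under a disease episode), the
#' contact takes the episode's code. Contacts without an episode link, or
#' with a dangling link, are unchanged (a dangling link warns).
#'
#' @param journal_contacts Journal table with columns `pseudo_id` (or
#'   `true_id`), `date`, `icpc`, `episode_key`.
#' @param episode_records Episode table with columns `episode_key`, `icpc`.
#' @return The journal table with overruled `icpc` values.
#' @export
apply_symptom_overrule <- function(journal_contacts, episode_records) {
  if (nrow(journal_contacts) == 0) {
    return(journal_contacts)
  }
  ep <- episode_records[, c("episode_key", "icpc")]
  names(ep)[2] <- "episode_icpc"
  ep <- dplyr::distinct(ep, .data$episode_key, .keep_all = TRUE)
  out <- dplyr::left_join(journal_contacts, ep, by = "episode_key")
  dangling <- !is.na(out$episode_key) & is.na(out$episode_icpc)
  if (any(dangling)) {
    rlang::warn(sprintf(
      "%d journal contact(s) reference a missing episode; left unchanged",
      sum(dangling)
    ))
  }
  out$icpc <- ifelse(
    !is.na(out$episode_icpc), out$episode_icpc, out$icpc
  )
  out$episode_icpc <- NULL
  out
}
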