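#' The regular consultation and visit claims codes
#'
#' The five insurance-claims codes representing ordinary GP consultations
#' and home visits: 12001 (consultation > 20 min), 12002 (visit < 20 min),
#' 12003 (visit > 20 min), 12010 (consultation < 5 min) and 12011
#' (consultation 5-20 min). This code set is processed identically by both
#' shipped rule-sets.
#'
#' @return A character vector of five codes.
#' @export
regular_consult_codes <- function() {
  c("12001", "12002", "12003", "12010", "12011")
}

#' ETL rule-set configuration
#'
#' Bundles every database-zone processing choice that distinguishes one
#' research registry's pipeline from another's: how registration quarters
#' are derived, which identifier the pseudonym is built from, whether and
#' how insurance-claims codes are filtered, the prescription deduplication
#' window and source handling, and whether episodes are taken as recorded
#' or rebuilt with the episode-of-care construct.
#'
#' @param name Label for the rule-set.
#' @param quarter_rule `"from_enrollment_date"` (only quarters fully
#'   covered by the enrollment span count; mid-quarter enrollment starts
#'   the next quarter) or `"from_capitation_imputed"` (quarters with a
#'   capitation fee record; gaps between the first and last fee are
#'   imputed).
#' @param pseudonym_scheme `"pc3_birthyear_sex"` (keyed hash of the first
#'   three postal-code digits, birth year and sex; collision-prone) or
#'   `"ssn"` (keyed hash of the social security number; absent when the
#'   number is missing).
#' @param claims_filter `"all"` or an explicit character vector of claims
#'   codes retained for the research dataset.
#' @param contact_codes_filter Optional code set used before contact
#'   derivation; defaults to `claims_filter`.
#' @param dedup_window_days Non-negative integer; records of the same ATC
#'   for the same patient within this many days of the last kept record
#'   are dropped. `0` disables the deduplication stage.
#' @param include_pharmacy_prescriptions Keep prescription records
#'   originating from pharmacy feedback.
#' @param episode_mode `"recorded"` (episodes of care as recorded in the
#'   EHR) or `"construct"` (episodes rebuilt from coded encounters over a
#'   lookback window).
#' @param lookback_years Years of history before the analysis year used by
#'   the construct.
#' @param contact_free_interval_days Named numeric vector mapping ICPC
#'   codes to their contact-free interval in days.
#' @param contact_free_interval_default Interval used for codes not in the
#'   map.
#' @param chronic_codes ICPC codes whose construct episodes never close.
#' @param collision_policy What to do when two patients share a pseudonym:
#'   `"drop"` removes all patients with an ambiguous pseudonym (the
#'   default; population rates are unaffected because ambiguity is
#'   unrelated to morbidity), `"collapse"` merges them into one patient
#'   with the union of events and quarters.
#' @param salt Keying string for the pseudonym hash; defaults to `name` so
#'   the two rule-sets produce unrelated pseudonym spaces.
#'
#' @return An object of class `pipeline_config`.
#' @seealso [ahon_style()], [nivel_style()], [run_pipeline()]
#' @export
pipeline_config <- function(name,
                            quarter_rule = c(
                              "from_enrollment_date",
                              "from_capitation_imputed"
                            ),
                            pseudonym_scheme = c("pc3_birthyear_sex", "ssn"),
                            claims_filter = "all",
                            contact_codes_filter = NULL,
                            dedup_window_days = 0L,
                            include_pharmacy_prescriptions = FALSE,
                            episode_mode = c("recorded", "construct"),
                            lookback_years = 2L,
                            contact_free_interval_days = c(U71 = 28, R05 = 90),
                            contact_free_interval_default = 90,
                            chronic_codes = c("T90", "K86"),
                            collision_policy = c("drop", "collapse"),
                            salt = name) {
  cfg <- list(
    name = name,
    quarter_rule = match.arg(quarter_rule),
    pseudonym_scheme = match.arg(pseudonym_scheme),
    claims_filter = claims_filter,
    contact_codes_filter = contact_codes_filter,
    dedup_window_days = as.integer(dedup_window_days),
    include_pharmacy_prescriptions = isTRUE(include_pharmacy_prescriptions),
    episode_mode = match.arg(episode_mode),
    lookback_years = as.integer(lookback_years),
    contact_free_interval_days = contact_free_interval_days,
    contact_free_interval_default = contact_free_interval_default,
    chronic_codes = chronic_codes,
    collision_policy = match.arg(collision_policy),
    salt = salt
  )
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

#' Validate an ETL rule-set configuration
#'
#' @param config A `pipeline_config`.
#' @return The configuration, invisibly, if valid.
#' @export
validate_pipeline_config <- function(config) {
  check_count(config$dedup_window_days, "dedup_window_days")
  check_count(config$lookback_years, "lookback_years")
  iv <- config$contact_free_interval_days
  if (length(iv) > 0 && (any(iv <= 0) || is.null(names(iv)))) {
    abort_invalid(
      "contact_free_interval_days",
      "must be a named vector of positive day counts"
    )
  }
  if (!is.numeric(config$contact_free_interval_default) ||
    config$contact_free_interval_default <= 0) {
    abort_invalid("contact_free_interval_default", "must be a positive duration")
  }
  if (!identical(config$claims_filter, "all") &&
    !is.character(config$claims_filter)) {
    abort_invalid("claims_filter", "must be \"all\" or a character code set")
  }
  invisible(config)
}

#' Shipped rule-set: minimal-processing registry style
#'
#' Registration quarters from the enrollment date, pseudonym from
#' (postal-code prefix, birth year, sex), all insurance-claims codes kept,
#' no prescription deduplication, GP-recorded prescriptions only, episodes
#' as recorded in the EHR.
#'
#' @return A `pipeline_config`.
#' @export
ahon_style <- function() {
  pipeline_config(
    name = "ahon_style",
    quarter_rule = "from_enrollment_date",
    pseudonym_scheme = "pc3_birthyear_sex",
    claims_filter = "all",
    dedup_window_days = 0L,
    include_pharmacy_prescriptions = FALSE,
    episode_mode = "recorded"
  )
}

#' Shipped rule-set: extensively-processed registry style
#'
#' Registration quarters from capitation fee records with gap imputation,
#' pseudonym from the social security number, claims filtered to a
#' study-relevant code selection, 8-day prescription deduplication with
#' pharmacy feedback included, and episodes rebuilt with the
#' episode-of-care construct over a 2-year lookback.
#'
#' @return A `pipeline_config`.
#' @export
nivel_style <- function() {
  pipeline_config(
    name = "nivel_style",
    quarter_rule = "from_capitation_imputed",
    pseudonym_scheme = "ssn",
    claims_filter = c(regular_consult_codes(), "12004", "12024", "13012"),
    dedup_window_days = 8L,
    include_pharmacy_prescriptions = TRUE,
    episode_mode = "construct",
    lookback_years = 2L
  )
}

#' Read / write a rule-set configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_pipeline_config()] returns a `pipeline_config`;
#'   [write_pipeline_config()] returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$contact_free_interval_days <- unlist(raw$contact_free_interval_days)
  raw$claims_filter <- unlist(raw$claims_filter)
  raw$chronic_codes <- unlist(raw$chronic_codes)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  validate_pipeline_config(config)
  out <- unclass(config)
  out$contact_free_interval_days <- as.list(config$contact_free_interval_days)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("<pipeline_config: %s>\n", x$name))
  cat(sprintf(
    "  quarters: %s | pseudonym: %s | collisions: %s\n",
    x$quarter_rule, x$pseudonym_scheme, x$collision_policy
  ))
  filt <- if (identical(x$claims_filter, "all")) {
    "all codes"
  } else {
    sprintf("%d codes", length(x$claims_filter))
  }
  cat(sprintf(
    "  claims filter: %s | dedup window: %d d | pharmacy rx: %s\n",
    filt, x$dedup_window_days,
    ifelse(x$include_pharmacy_prescriptions, "kept", "dropped")
  ))
  cat(sprintf(
    "  episodes: %s (lookback %d y)\n", x$episode_mode, x$lookback_years
  ))
  invisible(x)
}
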