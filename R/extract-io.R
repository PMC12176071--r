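# CSV round-trip for raw extracts (UTF-8, header row, ISO-8601 dates).

extract_col_types <- function() {
  list(
    patients = readr::cols(
      true_id = readr::col_character(),
      practice_id = readr::col_character(),
      ssn = readr::col_character(),
      postal_code = readr::col_character(),
      birth_year = readr::col_integer(),
      sex = readr::col_character(),
      enrollment_date = readr::col_date(),
      disenrollment_date = readr::col_date()
    ),
    journal_contacts = readr::cols(
      true_id = readr::col_character(),
      date = readr::col_date(),
      icpc = readr::col_character(),
      episode_key = readr::col_character()
    ),
    claims_events = readr::cols(
      true_id = readr::col_character(),
      date = readr::col_date(),
      claims_code = readr::col_character(),
      icpc = readr::col_character()
    ),
    episodes = readr::cols(
      episode_key = readr::col_character(),
      true_id = readr::col_character(),
      icpc = readr::col_character(),
      start_date = readr::col_date(),
      end_date = readr::col_date(),
      chronic = readr::col_logical()
    ),
    prescriptions = readr::cols(
      true_id = readr::col_character(),
      date = readr::col_date(),
      atc = readr::col_character(),
      source = readr::col_character(),
      icpc_indication = readr::col_character()
    ),
    capitation = readr::cols(
      true_id = readr::col_character(),
      year = readr::col_integer(),
      quarter = readr::col_integer()
    )
  )
}

#' Write a raw EHR extract to a directory of CSV files
#'
#' One CSV per event table (`patients.csv`, `journal_contacts.csv`,
#' `claims_events.csv`, `episodes.csv`, `prescriptions.csv`,
#' `capitation.csv`) plus `meta.json`. Dates are ISO-8601;
#' [read_extract()] restores an identical object.
#'
#' @param extract A `raw_ehr_extract`.
#' @param directory Output directory (created if missing).
#' @return `directory`, invisibly.
#' @export
write_extract <- function(extract, directory) {
  stopifnot(inherits(extract, "raw_ehr_extract"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (tb in extract_table_names()) {
    readr::write_csv(extract[[tb]], file.path(directory, paste0(tb, ".csv")), na = "")
  }
  meta <- extract$meta
  meta$window_start <- format(meta$window_start)
  meta$window_end <- format(meta$window_end)
  jsonlite::write_json(meta, file.path(directory, "meta.json"), auto_unbox = TRUE)
  invisible(directory)
}

#' Read a raw EHR extract from a directory of CSV files
#'
#' Inverse of [write_extract()]. A missing table file or an unexpected
#' column set raises a format error naming the table (and column).
#'
#' @param directory Directory written by [write_extract()].
#' @return A `raw_ehr_extract`.
#' @export
read_extract <- function(directory) {
  types <- extract_col_types()
  tables <- list()
  for (tb in extract_table_names()) {
    path <- file.path(directory, paste0(tb, ".csv"))
    if (!file.exists(path)) {
      rlang::abort(
        sprintf("missing table file for \"%s\": %s", tb, path),
        class = "ehretl_format_error"
      )
    }
    got <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
      show_col_types = FALSE
    ))
    want <- names(types[[tb]]$cols)
    if (!setequal(got, want)) {
      bad <- c(setdiff(want, got), setdiff(got, want))
      rlang::abort(
        sprintf(
          "schema mismatch in table \"%s\": unexpected or missing column(s) %s",
          tb, paste(bad, collapse = ", ")
        ),
        class = "ehretl_format_error"
      )
    }
    tables[[tb]] <- readr::read_csv(path, col_types = types[[tb]],
      na = "", show_col_types = FALSE
    )
  }
  meta <- jsonlite::read_json(file.path(directory, "meta.json"),
    simplifyVector = TRUE
  )
  meta$window_start <- as.Date(meta$window_start)
  meta$window_end <- as.Date(meta$window_end)
  meta$analysis_year <- as.integer(meta$analysis_year)
  meta$seed <- as.integer(meta$seed)
  meta$row_counts <- lapply(meta$row_counts, as.integer)
  tables$meta <- meta
  class(tables) <- "raw_ehr_extract"
  tables
}
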