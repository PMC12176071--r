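# Shared internal helpers: date/quarter arithmetic, validation, hashing.

quarter_start <- function(year, q) {
  as.Date(sprintf("%d-%02d-01", year, (q - 1L) * 3L + 1L))
}

quarter_end <- function(year, q) {
  ny <- ifelse(q == 4L, year + 1L, year)
  nq <- ifelse(q == 4L, 1L, q + 1L)
  quarter_start(ny, nq) - 1L
}

year_of <- function(d) as.integer(format(d, "%Y"))

#' @noRd
abort_invalid <- function(field, msg) {
  rlang::abort(
    sprintf("invalid `%s`: %s", field, msg),
    class = "ehretl_validation_error"
  )
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort_invalid(field, "must be a single probability in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort_invalid(field, sprintf("must be a single integer >= %d", min))
  }
  invisible(x)
}

# Deterministic keyed hash used for pseudonyms; stable across sessions.
keyed_hash <- function(keys) {
  out <- rep(NA_character_, length(keys))
  ok <- !is.na(keys)
  out[ok] <- vapply(keys[ok], rlang::hash, character(1), USE.NAMES = FALSE)
  out
}

# Age band used throughout: 0-4, 5-17, 18-64, 65+.
age_band_levels <- function() c("0-4", "5-17", "18-64", "65+")

age_to_band <- function(age) {
  cut(age,
    breaks = c(-Inf, 4, 17, 64, Inf),
    labels = age_band_levels()
  ) |> as.character()
}

`%||%` <- function(x, y) if (is.null(x)) y else x
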