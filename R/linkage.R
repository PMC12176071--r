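#' Resolve pseudonyms to platform identifiers
#'
#' Models the resolution step of a trusted data platform that assigns one
#' identifier per person across datasets. Pseudonyms derived from the
#' social security number resolve deterministically. Pseudonyms derived
#' from (postal-code prefix, birth year, sex) resolve only when that
#' triple is unique within the registry; an ambiguous triple cannot be
#' attributed to a person and resolves to absent, modelling linkage loss.
#'
#' @param pseudo_id Character vector of pseudonyms to resolve.
#' @param scheme Pseudonym scheme the pseudonyms were built with.
#' @param registry The population register: a patient table with `true_id`
#'   and the scheme's source fields.
#' @param salt Keying string used when the pseudonyms were built.
#' @return Character vector of platform identifiers, `NA` where
#'   unresolvable.
#' @export
platform_identifier <- function(pseudo_id,
                                scheme = c("pc3_birthyear_sex", "ssn"),
                                registry,
                                salt = "") {
  scheme <- match.arg(scheme)
  reg_pseudo <- pseudonymize(registry, scheme, salt)
  map <- tibble::tibble(pseudo = reg_pseudo, platform = registry$true_id)
  map <- map[!is.na(map$pseudo), ]
  if (scheme == "pc3_birthyear_sex") {
    ambiguous <- unique(map$pseudo[duplicated(map$pseudo)])
    map <- map[!map$pseudo %in% ambiguous, ]
  }
  map$platform[match(pseudo_id, map$pseudo)]
}

#' Concordant patients between two processed datasets
#'
#' Identifies the patients present in both datasets through their platform
#' identifiers, reports the population flow (counts in each dataset, in
#' both, and in their union), and returns both datasets restricted to the
#' concordant patients.
#'
#' Patients without a platform identifier cannot be matched and count as
#' dataset-specific members of the union.
#'
#' @param ds_a,ds_b `processed_dataset` objects carrying `platform_id`.
#' @return An object of class `concordant_link`: `shared_ids`, `n_a`,
#'   `n_b`, `n_shared`, `n_a_only`, `n_b_only`, `n_union`,
#'   `concordant_fraction`, and the restricted datasets `ds_a`, `ds_b`.
#' @export
concordant <- function(ds_a, ds_b) {
  ids_a <- ds_a$patients$platform_id
  ids_b <- ds_b$patients$platform_id
  link <- concordance_counts(ids_a, ids_b)
  link$ds_a <- restrict_to_platform_ids(ds_a, link$shared_ids)
  link$ds_b <- restrict_to_platform_ids(ds_b, link$shared_ids)
  link
}

#' Population-flow arithmetic for two identifier sets
#'
#' The counts-only core of [concordant()]: given the platform identifiers
#' of each dataset (`NA` = unlinkable), computes the shared,
#' dataset-specific and union counts and the concordant fraction
#' `n_shared / n_union`.
#'
#' @param ids_a,ids_b Character vectors of platform identifiers.
#' @return A `concordant_link` (without restricted datasets).
#' @export
concordance_counts <- function(ids_a, ids_b) {
  known_a <- unique(ids_a[!is.na(ids_a)])
  known_b <- unique(ids_b[!is.na(ids_b)])
  shared <- intersect(known_a, known_b)
  n_a <- length(ids_a)
  n_b <- length(ids_b)
  n_shared <- length(shared)
  n_union <- length(union(known_a, known_b)) +
    sum(is.na(ids_a)) + sum(is.na(ids_b))
  out <- list(
    shared_ids = shared,
    n_a = n_a,
    n_b = n_b,
    n_shared = n_shared,
    n_a_only = n_a - n_shared,
    n_b_only = n_b - n_shared,
    n_union = n_union,
    concordant_fraction = if (n_union > 0) n_shared / n_union else NA_real_
  )
  class(out) <- "concordant_link"
  out
}

restrict_to_platform_ids <- function(ds, ids) {
  keep <- ds$patients$platform_id %in% ids
  kept_pseudo <- ds$patients$pseudo_id[keep]
  out <- ds
  out$patients <- ds$patients[keep, ]
  for (tb in setdiff(processed_table_names(), "patients")) {
    out[[tb]] <- ds[[tb]][ds[[tb]]$pseudo_id %in% kept_pseudo, ]
  }
  out
}

#' @export
print.concordant_link <- function(x, ...) {
  cat("<concordant_link>\n")
  cat(sprintf(
    "  A: %s | B: %s | shared: %s | union: %s\n",
    format(x$n_a, big.mark = ","), format(x$n_b, big.mark = ","),
    format(x$n_shared, big.mark = ","), format(x$n_union, big.mark = ",")
  ))
  cat(sprintf("  concordant fraction: %.3f\n", x$concordant_fraction))
  invisible(x)
}

#' Serialize a concordance report to JSON
#'
#' @param link A `concordant_link`.
#' @param path Output path for a JSON object with the flow counts.
#' @return `path`, invisibly.
#' @export
write_link_report <- function(link, path) {
  jsonlite::write_json(
    list(
      n_a = link$n_a, n_b = link$n_b, n_shared = link$n_shared,
      n_union = link$n_union, fraction = link$concordant_fraction
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
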