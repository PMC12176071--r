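test_that("enrollment-date quarter rule counts only fully covered quarters", {
  expect_equal(
    quarters_from_enrollment(as.Date("2019-01-01"), analysis_year = 2019),
    1:4
  )
  expect_equal(
    quarters_from_enrollment(as.Date("2019-02-15"), analysis_year = 2019),
    2:4
  )
  expect_equal(
    quarters_from_enrollment(as.Date("2019-11-20"), analysis_year = 2019),
    integer(0)
  )
  # disenrollment before the quarter's last day loses that quarter
  expect_equal(
    quarters_from_enrollment(
      as.Date("2018-01-01"), as.Date("2019-08-15"), 2019
    ),
    1:2
  )
  expect_error(
    quarters_from_enrollment(
      as.Date("2019-05-01"), as.Date("2019-01-01"), 2019
    ),
    "disenrollment_date"
  )

  # exhaustive sweep over every enrollment day of 2019, open-ended
  q_first_days <- as.Date(c(
    "2019-01-01", "2019-04-01", "2019-07-01", "2019-10-01"
  ))
  for (d in seq(as.Date("2019-01-01"), as.Date("2019-12-31"), by = 1)) {
    d <- as.Date(d, origin = "1970-01-01")
    expected <- which(d <= q_first_days)
    expect_identical(
      quarters_from_enrollment(d, analysis_year = 2019), expected
    )
  }
})

test_that("capitation quarter rule imputes gaps between first and last fee", {
  cap <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    tibble::tibble(year = m[, 1], quarter = m[, 2])
  }
  expect_equal(quarters_from_capitation(cap(2019, 1, 2019, 4), 2019), 1:4)
  expect_equal(quarters_from_capitation(cap(2019, 2), 2019), 2L)
  expect_equal(
    quarters_from_capitation(cap(2018, 4, 2019, 2), 2019), 1:2
  )
  expect_equal(
    quarters_from_capitation(
      tibble::tibble(year = integer(), quarter = integer()), 2019
    ),
    integer(0)
  )

  # brute-force fill-between oracle + monotonicity + contiguity
  set.seed(101)
  for (rep in 1:200) {
    k <- sample(0:5, 1)
    qs <- tibble::tibble(
      year = sample(2017:2020, k, replace = TRUE),
      quarter = sample(1:4, k, replace = TRUE)
    )
    got <- quarters_from_capitation(qs, 2019)
    if (k == 0) {
      expect_identical(got, integer(0))
      next
    }
    all_q <- tidyr::expand_grid(year = 2016:2021, quarter = 1:4) |>
      dplyr::mutate(idx = dplyr::row_number())
    obs <- dplyr::inner_join(all_q, qs, by = c("year", "quarter"))
    filled <- all_q[all_q$idx >= min(obs$idx) & all_q$idx <= max(obs$idx), ]
    expected <- filled$quarter[filled$year == 2019]
    expect_identical(got, as.integer(expected))
    # contiguous run
    if (length(got) > 1) expect_true(all(diff(got) == 1))
    # adding a quarter never shrinks the set
    extra <- dplyr::bind_rows(
      qs, tibble::tibble(year = 2019L, quarter = sample(1:4, 1))
    )
    expect_true(all(got %in% quarters_from_capitation(extra, 2019)))
  }
})

test_that("pseudonyms are deterministic, collide by construction, absent when unsourced", {
  pats <- mk_patients(
    n = 3,
    ssn = c("ssn1", NA, "ssn3"),
    postal_code = c("1234AB", "1234XY", "5678AB"),
    birth_year = c(1980L, 1980L, 1980L),
    sex = "female"
  )
  pc <- pseudonymize(pats, "pc3_birthyear_sex", salt = "k")
  expect_identical(pc[1], pc[2]) # same PC3 "123", birth year, sex
  expect_false(pc[1] == pc[3])
  expect_identical(pc, pseudonymize(pats, "pc3_birthyear_sex", salt = "k"))
  expect_false(any(
    pc == pseudonymize(pats, "pc3_birthyear_sex", salt = "other")
  ))

  ss <- pseudonymize(pats, "ssn", salt = "k")
  expect_true(is.na(ss[2]))
  expect_false(is.na(ss[1]))
  expect_identical(ss, pseudonymize(pats, "ssn", salt = "k"))
})

test_that("claims filtering is an exact set-membership scan", {
  claims <- tibble::tibble(
    pseudo_id = "p1",
    date = as.Date("2019-01-01") + 0:9,
    claims_code = c(
      "12010", "13012", "12011", "12001", "12345",
      "12002", "12003", "13034", "12010", "12004"
    ),
    icpc = NA_character_
  )
  expect_identical(filter_claims(claims, "all"), claims)
  expect_equal(nrow(filter_claims(claims, c("12010", "12011"))), 3)
  expect_warning(out <- filter_claims(claims, character(0)), "empty")
  expect_equal(nrow(out), 0)

  set.seed(3)
  codes <- sample(c("12010", "12011", "13012", "99999"), 200, replace = TRUE)
  tab <- tibble::tibble(
    pseudo_id = "p", date = as.Date("2019-01-01"), claims_code = codes,
    icpc = NA_character_
  )
  keep <- regular_consult_codes()
  expect_equal(
    nrow(filter_claims(tab, keep)),
    sum(vapply(codes, function(cc) cc %in% keep, logical(1)))
  )
})

test_that("contacts collapse to at most one per patient per day", {
  claims <- tibble::tibble(
    pseudo_id = "p1",
    date = as.Date(c(rep("2019-03-01", 3), "2019-03-02")),
    claims_code = c("12010", "13012", "12011", "12001")
  )
  expect_equal(nrow(derive_contacts(claims)), 2)
  expect_equal(nrow(derive_contacts(claims[0, ])), 0)

  set.seed(4)
  tab <- tibble::tibble(
    pseudo_id = sample(letters[1:5], 300, replace = TRUE),
    date = as.Date("2019-01-01") + sample(0:30, 300, replace = TRUE),
    claims_code = "12010"
  )
  expect_equal(
    nrow(derive_contacts(tab)),
    length(unique(paste(tab$pseudo_id, tab$date)))
  )
})

test_that("prescription dedup follows the greedy last-kept scan", {
  rx <- function(days, atc = "A", id = "p1") {
    tibble::tibble(
      pseudo_id = id, date = as.Date("2019-03-01") + days, atc = atc
    )
  }
  expect_equal(
    dedupe_prescriptions(rx(c(0, 4)), 8)$date,
    as.Date("2019-03-01")
  )
  # day 7 dropped; day 14 is more than 8 days after the last kept (day 0)
  expect_equal(
    dedupe_prescriptions(rx(c(0, 7, 14)), 8)$date,
    as.Date("2019-03-01") + c(0, 14)
  )
  # different ATC codes are never merged
  two <- dplyr::bind_rows(rx(0, "A"), rx(1, "B"))
  expect_equal(nrow(dedupe_prescriptions(two, 8)), 2)
  # window 0 collapses only exact same-day duplicates
  expect_equal(nrow(dedupe_prescriptions(rx(c(0, 0, 1)), 0)), 2)

  # idempotence and non-increase on random tables
  set.seed(9)
  for (rep in 1:25) {
    tab <- tibble::tibble(
      pseudo_id = sample(c("p1", "p2"), 12, replace = TRUE),
      date = as.Date("2019-01-01") + sample(0:20, 12, replace = TRUE),
      atc = sample(c("A", "B"), 12, replace = TRUE)
    )
    w <- sample(c(0, 3, 8), 1)
    once <- dedupe_prescriptions(tab, w)
    expect_lte(nrow(once), nrow(tab))
    expect_equal(dedupe_prescriptions(once, w), once)
    # agreement with the sequential reference scan, per group
    for (g in split(once, paste(once$pseudo_id, once$atc))) {
      orig <- tab[tab$pseudo_id == g$pseudo_id[1] & tab$atc == g$atc[1], ]
      expect_equal(sort(g$date), ref_dedupe_dates(orig$date, w))
    }
  }
})

test_that("recorded episodes pass through on analysis-year overlap", {
  eps <- tibble::tibble(
    pseudo_id = "p1",
    icpc = c("R96", "A01", "T90"),
    start_date = as.Date(c("2018-06-01", "2017-01-01", "2019-05-01")),
    end_date = as.Date(c(NA, "2017-12-31", "2019-06-30"))
  )
  out <- episodes_recorded(eps, 2019)
  expect_setequal(out$icpc, c("R96", "T90"))

  set.seed(12)
  starts <- as.Date("2017-01-01") + sample(0:1000, 100, replace = TRUE)
  ends <- starts + sample(c(NA, 0:400), 100, replace = TRUE)
  tab <- tibble::tibble(
    pseudo_id = "p", icpc = "X01", start_date = starts, end_date = ends
  )
  got <- episodes_recorded(tab, 2019)
  oracle <- tab[
    tab$start_date <= as.Date("2019-12-31") &
      (is.na(tab$end_date) | tab$end_date >= as.Date("2019-01-01")),
  ]
  expect_equal(nrow(got), nrow(oracle))
})

test_that("the episode construct splits on the contact-free interval and adds half-interval tails", {
  jc <- function(dates, icpc, id = "p1") {
    tibble::tibble(pseudo_id = id, date = as.Date(dates), icpc = icpc)
  }
  no_rx <- tibble::tibble(
    pseudo_id = character(), date = as.Date(character()),
    icpc_indication = character()
  )

  out <- episodes_construct(
    jc(c("2019-01-10", "2019-02-10"), "R05"), no_rx,
    analysis_year = 2019, interval_map = c(R05 = 90), chronic_codes = character()
  )
  expect_equal(nrow(out), 1)
  expect_equal(out$start_date, as.Date("2019-01-10"))
  expect_equal(out$end_date, as.Date("2019-03-27")) # 2019-02-10 + 45

  out <- episodes_construct(
    jc("2019-05-01", "U71"), no_rx,
    analysis_year = 2019, interval_map = c(U71 = 28), chronic_codes = character()
  )
  expect_equal(out$end_date, as.Date("2019-05-15")) # + floor(28 / 2)

  out <- episodes_construct(
    jc(c("2019-01-10", "2019-07-29"), "R05"), no_rx, # 200 days apart
    analysis_year = 2019, interval_map = c(R05 = 90), chronic_codes = character()
  )
  expect_equal(nrow(out), 2)

  # chronic codes never close and survive from earlier years
  out <- episodes_construct(
    jc("2017-03-05", "T90"), no_rx,
    analysis_year = 2019, chronic_codes = "T90"
  )
  expect_equal(nrow(out), 1)
  expect_true(is.na(out$end_date))

  # prescriptions with an indication contribute encounters
  rx <- tibble::tibble(
    pseudo_id = "p1", date = as.Date("2019-04-01"), icpc_indication = "R05"
  )
  out <- episodes_construct(
    jc("2019-01-10", "R05"), rx,
    analysis_year = 2019, interval_map = c(R05 = 90), chronic_codes = character()
  )
  expect_equal(nrow(out), 1)
  expect_equal(out$end_date, as.Date("2019-04-01") + 45)

  # codes missing from the interval map fall back to the default, noted once
  expect_message(
    episodes_construct(
      jc("2019-01-10", "Z99"), no_rx,
      analysis_year = 2019, interval_map = c(R05 = 90),
      interval_default = 60, chronic_codes = character()
    ),
    "Z99"
  )
})

test_that("symptoms recorded under an episode take the episode's code", {
  jc <- tibble::tibble(
    pseudo_id = "p1",
    date = as.Date("2019-02-01") + 0:2,
    icpc = c("R05", "R05", "A04"),
    episode_key = c("ep-asthma", "ep-cough", NA)
  )
  eps <- tibble::tibble(
    episode_key = c("ep-asthma", "ep-cough"),
    icpc = c("R96", "R05")
  )
  out <- apply_symptom_overrule(jc, eps)
  expect_equal(out$icpc, c("R96", "R05", "A04"))

  dangling <- jc
  dangling$episode_key[1] <- "gone"
  expect_warning(out2 <- apply_symptom_overrule(dangling, eps), "missing")
  expect_equal(out2$icpc, jc$icpc)
})

test_that("run_pipeline composes the stages per configuration", {
  pats <- mk_patients(
    n = 3,
    ssn = c("s1", NA, "s3"),
    postal_code = c("1111AA", "2222BB", "3333CC"),
    enrollment_date = as.Date(c("2015-01-01", "2015-01-01", "2019-02-15"))
  )
  rx <- tibble::tibble(
    true_id = c("pt01", "pt01", "pt02"),
    date = as.Date(c("2019-03-01", "2019-03-04", "2019-05-01")),
    atc = "A10BA02",
    source = c("gp", "pharmacy", "gp"),
    icpc_indication = NA_character_
  )
  ex <- mk_extract(patients = pats, prescriptions = rx)

  # ssn scheme drops the patient without a number
  nv <- run_pipeline(ex, nivel_style())
  expect_equal(nrow(nv$patients), 2)

  # pharmacy rows dropped without include_pharmacy; kept and deduped with it
  ah <- run_pipeline(ex, ahon_style())
  expect_equal(nrow(ah$prescriptions), 2) # both GP records, pharmacy row gone
  expect_equal(nrow(nv$prescriptions), 1) # pt01's re-record deduped; pt02 absent

  # mid-quarter enrollee only from Q2; patient pt03 retains 3 quarters
  p3 <- ah$patients[ah$patients$platform_id == "pt03", ]
  expect_equal(p3$n_quarters, 3L)
  expect_equal(p3$patient_years, 0.75)

  # identical configurations give identical datasets
  again <- run_pipeline(ex, ahon_style())
  expect_identical(ah$patients, again$patients)
  expect_identical(ah$prescriptions, again$prescriptions)
})

test_that("pseudonym collisions are dropped or collapsed per policy", {
  pats <- mk_patients(
    n = 3,
    ssn = c("s1", "s2", "s3"),
    postal_code = c("1234AB", "1234ZZ", "9999XX"), # pt01/pt02 share PC3 "123"
    birth_year = 1980L, sex = "female"
  )
  claims <- tibble::tibble(
    true_id = c("pt01", "pt02", "pt03"),
    date = as.Date(c("2019-01-10", "2019-01-11", "2019-01-12")),
    claims_code = "12010", icpc = NA_character_
  )
  ex <- mk_extract(patients = pats, claims_events = claims)

  dropped <- run_pipeline(
    ex, pipeline_config("drop_cfg", pseudonym_scheme = "pc3_birthyear_sex")
  )
  expect_equal(nrow(dropped$patients), 1)
  expect_equal(nrow(dropped$contacts), 1)

  collapsed <- run_pipeline(
    ex,
    pipeline_config("coll_cfg",
      pseudonym_scheme = "pc3_birthyear_sex",
      collision_policy = "collapse"
    )
  )
  expect_equal(nrow(collapsed$patients), 2)
  # merged patient keeps the union of events but is unlinkable
  merged <- collapsed$patients[is.na(collapsed$patients$platform_id), ]
  expect_equal(nrow(merged), 1)
  expect_equal(
    sum(collapsed$contacts$pseudo_id == merged$pseudo_id), 2
  )
})
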