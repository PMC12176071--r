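test_that("patient-years sum registration quarters at 0.25 each", {
  ds <- mk_processed(mk_ds_patients(4, n_quarters = 4L))
  expect_equal(patient_years_total(ds), 4)
  one <- mk_processed(mk_ds_patients(1, n_quarters = 1L))
  expect_equal(patient_years_total(one), 0.25)
})

test_that("prevalence and event rates per 1000 patient-years", {
  expect_equal(round(prevalence_rate(2979, 46400), 1), 64.2)
  expect_equal(prevalence_rate(0, 100), 0)
  expect_error(prevalence_rate(5, 0), "patient_years")
  expect_equal(rate_per_1000py(100, 50), 2000)
  expect_equal(rate_per_1000py(0, 50), 0)
  expect_error(rate_per_1000py(5, -1), "patient_years")
})

test_that("demographics match a brute-force group-by", {
  pats <- mk_ds_patients(
    n = 40,
    practice_id = rep(c("pr01", "pr02"), 20),
    age_band = sample(c("0-4", "5-17", "18-64", "65+"), 40, replace = TRUE),
    sex = sample(c("male", "female"), 40, replace = TRUE),
    n_quarters = sample(1:4, 40, replace = TRUE)
  )
  ds <- mk_processed(pats)
  tab <- demographics_table(ds)
  get <- function(ch) tab$value[tab$characteristic == ch]
  expect_equal(get("patients"), 40)
  expect_equal(get("patient_years"), sum(pats$patient_years))
  expect_equal(get("patients_per_practice_mean"), 20)
  for (b in c("0-4", "5-17", "18-64", "65+")) {
    expect_equal(get(paste0("age_band:", b)), sum(pats$age_band == b))
  }
  expect_equal(get("sex:male"), sum(pats$sex == "male"))
  # percentages over the total, one decimal
  expect_equal(
    tab$pct[tab$characteristic == "sex:male"],
    round(100 * sum(pats$sex == "male") / 40, 1)
  )

  solo <- mk_processed(mk_ds_patients(3, age_band = "65+"))
  stab <- demographics_table(solo)
  expect_equal(stab$pct[stab$characteristic == "age_band:65+"], 100)
  expect_equal(stab$pct[stab$characteristic == "age_band:0-4"], 0)
})

test_that("per-patient indicators count events with zeros for quiet patients", {
  pats <- mk_ds_patients(3)
  claims <- tibble::tibble(
    pseudo_id = c("ps01", "ps01", "ps01"),
    date = as.Date(c("2019-02-01", "2019-02-01", "2019-02-02")),
    claims_code = c("12010", "13012", "12001"),
    icpc = NA_character_
  )
  contacts <- derive_contacts(claims)
  ds <- mk_processed(pats, contacts = contacts, claims = claims)

  rc <- per_patient_indicator(ds, "regular_consults")
  expect_equal(rc$n[rc$pseudo_id == "ps01"], 2)
  expect_equal(rc$n[rc$pseudo_id == "ps02"], 0)
  expect_error(per_patient_indicator(ds, "nonsense"), "indicator")

  # brute-force oracle on a generated dataset
  ex <- generate_extract(small_gen_config(seed = 13L))
  dsa <- run_pipeline(ex, ahon_style())
  for (ind in c("contacts", "regular_consults", "prescriptions", "episodes")) {
    got <- per_patient_indicator(dsa, ind)
    events <- switch(ind,
      contacts = dsa$contacts[, c("pseudo_id", "date")],
      regular_consults = unique(
        dsa$claims[
          dsa$claims$claims_code %in% regular_consult_codes(),
          c("pseudo_id", "date")
        ]
      ),
      prescriptions = dsa$prescriptions,
      episodes = dsa$episodes
    )
    brute <- table(factor(events$pseudo_id, levels = dsa$patients$pseudo_id))
    expect_equal(got$n[match(names(brute), got$pseudo_id)],
      as.integer(brute),
      ignore_attr = TRUE
    )
    expect_equal(sum(got$n), nrow(events))
  }
})

test_that("paired t test matches the closed form and flags degenerate input", {
  res <- paired_t_test(c(2, 4, 6), c(1, 2, 3), conf_level = 0.95)
  expect_equal(res$mean_diff, 2)
  expect_equal(res$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  tcrit <- stats::qt(0.975, df = 2)
  expect_equal(res$ci_low, 2 - tcrit / sqrt(3), tolerance = 1e-12)
  expect_equal(res$ci_high, 2 + tcrit / sqrt(3), tolerance = 1e-12)
  expect_false(res$degenerate)
  expect_true(res$ci_low <= res$mean_diff && res$mean_diff <= res$ci_high)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)
  expect_true(same$ci_low <= 0 && same$ci_high >= 0)

  short <- paired_t_test(1, 2)
  expect_true(short$degenerate)
})

test_that("standardized differences follow the pooled-proportion formula", {
  r <- standardized_difference(0.3, 0.2)
  expect_equal(r$sd_value, 0.1 / sqrt((0.3 * 0.7 + 0.2 * 0.8) / 2),
    tolerance = 1e-12
  )
  expect_equal(round(r$sd_value, 4), 0.2325)
  expect_true(r$significant)
  expect_equal(r$magnitude, "small")

  z <- standardized_difference(0.3, 0.3)
  expect_equal(z$sd_value, 0)
  expect_false(z$significant)
  expect_equal(z$magnitude, "negligible")

  expect_equal(standardized_difference(0.6, 0.3)$magnitude, "medium")
  expect_equal(standardized_difference(0.8, 0.3)$magnitude, "large")

  expect_error(standardized_difference(0, 0), "degenerate")
  expect_error(standardized_difference(1, 0), "degenerate")
  expect_error(standardized_difference(1.2, 0.5), "0, 1")

  set.seed(5)
  for (rep in 1:50) {
    p <- runif(2, 0.05, 0.95)
    expect_equal(
      standardized_difference(p[1], p[2])$sd_value,
      -standardized_difference(p[2], p[1])$sd_value
    )
  }
})

test_that("diagnosis-group indicators equal a brute-force recomputation", {
  spec <- default_diagnosis_groups()[[1]] # T90, A10A/A10B
  pats <- mk_ds_patients(4, n_quarters = c(4L, 4L, 2L, 4L))
  journal <- tibble::tibble(
    pseudo_id = c("ps01", "ps01", "ps03"),
    date = as.Date(c("2019-01-05", "2019-06-01", "2019-03-01")),
    icpc = c("T90", "T90", "T90")
  )
  rx <- tibble::tibble(
    pseudo_id = c("ps01", "ps03", "ps03", "ps02"),
    date = as.Date("2019-04-01"),
    atc = c("A10AB01", "A10BA02", "C10AA05", "A10BA02")
  )
  claims <- tibble::tibble(
    pseudo_id = c("ps01", "ps01", "ps02"),
    date = as.Date(c("2019-02-01", "2019-02-01", "2019-02-03")),
    claims_code = c("12010", "12011", "12010"),
    icpc = NA_character_
  )
  ds <- mk_processed(pats, claims = claims, prescriptions = rx, journal = journal)

  rep1 <- diagnosis_group_report(ds, spec)
  expect_equal(rep1$n_cases, 2) # ps01 counted once, ps03 once; ps02 no T90
  expect_equal(rep1$group_py, 1 + 0.5)
  expect_equal(rep1$prevalence, 2 / 3.5 * 1000)
  # prescriptions: prefix match on the cases only (ps02's A10 row excluded)
  expect_equal(rep1$rx_per_1000py, 2 / 3.5 * 1000)
  # consults: distinct patient-days of the cases with a regular code
  expect_equal(rep1$consults_per_1000py, 1 / 3.5 * 1000)

  rep2 <- diagnosis_group_report(ds, spec, denominator = "group_py")
  expect_equal(rep2$rx_per_1000py, 2 / 1.5 * 1000)

  empty_spec <- list(label = "none", icpc_code = "Z99", atc_prefixes = "Z99")
  rep3 <- diagnosis_group_report(ds, empty_spec)
  expect_equal(rep3$n_cases, 0)
  expect_equal(rep3$prevalence, 0)
})

test_that("comparing a dataset with itself yields exact zeros everywhere", {
  ex <- generate_extract(small_gen_config(seed = 17L))
  a1 <- run_pipeline(ex, ahon_style())
  a2 <- run_pipeline(ex, ahon_style())
  rep <- compare_datasets(a1, a2)
  expect_equal(rep$flow$concordant_fraction, 1)
  expect_true(all(rep$table2$mean_diff == 0))
  expect_true(all(rep$table2$p_value == 1))
  expect_true(all(rep$table3$sd_value == 0))
  expect_false(any(rep$table3$significant))
})

test_that("comparison reports survive a serialization round trip", {
  ex <- generate_extract(small_gen_config(seed = 19L))
  a <- run_pipeline(ex, ahon_style())
  b <- suppressMessages(run_pipeline(ex, nivel_style()))
  rep <- compare_datasets(a, b)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  back <- read_report(dir)
  expect_equal(
    as.data.frame(back$table2), as.data.frame(rep$table2),
    tolerance = 1e-12
  )
  expect_equal(
    as.data.frame(back$table3), as.data.frame(rep$table3),
    tolerance = 1e-12
  )
  expect_equal(back$flow$concordant_fraction, rep$flow$concordant_fraction)
  expect_true(file.exists(file.path(dir, "table1.csv")))
})
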