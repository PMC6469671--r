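idx <- day(0)

rec <- function(bundle) patient_record(bundle, "p1")

test_that("chronic rule applies dialect-specific code-depth thresholds", {
  # EMR: one code five years earlier suffices
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", -1825, "epilepsy"))
  expect_true(chronic_present(rec(b), "comorbidity:epilepsy", idx))
  # claims: four distinct dates fall short of five
  b <- test_bundle("CLAIMS_DOD", events = ev_spec("p1", -(1:4), "epilepsy"))
  expect_false(chronic_present(rec(b), "comorbidity:epilepsy", idx))
  # five dates with the fifth on the entry date itself
  b <- test_bundle("CLAIMS_DOD", events = ev_spec("p1", c(-40, -30, -20, -10, 0),
                                                  "epilepsy"))
  expect_true(chronic_present(rec(b), "comorbidity:epilepsy", idx))
  # any claims-positive record is EMR-positive (threshold ordering)
  expect_true(chronic_present(rec(b), "comorbidity:epilepsy", idx,
                              dialect = "EMR_CPRD"))
  # events after the index date never count
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", 5, "epilepsy"))
  expect_false(chronic_present(rec(b), "comorbidity:epilepsy", idx))
})

test_that("treated-pair rule is symmetric with a closed 90-day proximity", {
  pair <- function(dx_day, rx_day) {
    b <- test_bundle("EMR_CPRD", events = ev_spec("p1", dx_day, "depression"),
                     rx = rx_spec("p1", rx_day, "fluoxetine"))
    treated_pair_present(rec(b), "comorbidity:depression",
                         "medication:antidepressants", idx)
  }
  expect_true(pair(-100, -10))   # 90 days apart exactly
  expect_false(pair(-101, -10))  # 91 days apart
  expect_true(pair(-10, -40))    # prescription before diagnosis
  expect_false(pair(-10, 5))     # prescription after index ignored
})

test_that("cancer rules differ by dialect as published", {
  # claims: five codes inside six months
  b <- test_bundle("CLAIMS_DOD",
                   events = ev_spec("p1", -c(0, 30, 60, 90, 120), "cancer_primary"))
  expect_true(cancer_present(rec(b), idx))
  # nine codes each 200 days apart: no five-in-183-window, total < 10
  b <- test_bundle("CLAIMS_DOD",
                   events = ev_spec("p1", -200 * (0:8) - 10, "cancer_primary"))
  expect_false(cancer_present(rec(b), idx))
  expect_false(oracle_cancer_dod(b, "p1", idx))
  # ten codes at any spacing
  b <- test_bundle("CLAIMS_DOD",
                   events = ev_spec("p1", -200 * (0:9) - 10, "cancer_primary"))
  expect_true(cancer_present(rec(b), idx))
  # a single history-of-cancer code suffices in both dialects
  b <- test_bundle("CLAIMS_DOD", events = ev_spec("p1", -500, "cancer_history"))
  expect_true(cancer_present(rec(b), idx))
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", -500, "cancer_history"))
  expect_true(cancer_present(rec(b), idx))
  # EMR: one primary code suffices
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", -500, "cancer_primary"))
  expect_true(cancer_present(rec(b), idx))
})

test_that("acute window is a closed one-year look-back", {
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", -200, "uti"))
  expect_true(acute_window_present(rec(b), "infection:urinary_kidney", idx))
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", -400, "uti"))
  expect_false(acute_window_present(rec(b), "infection:urinary_kidney", idx))
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", 0, "uti"))
  expect_true(acute_window_present(rec(b), "infection:urinary_kidney", idx))
  expect_true(acute_window_present(rec(b), "infection:", idx))
})

test_that("hospitalized infections: inpatient claims vs EMR marker within a week", {
  b <- test_bundle("CLAIMS_DOD",
                   events = ev_spec("p1", -50, "respiratory_infection",
                                    setting = "inpatient"))
  expect_true(hospitalized_infection_present(rec(b), idx))
  b <- test_bundle("CLAIMS_DOD", events = ev_spec("p1", -50, "respiratory_infection"))
  expect_false(hospitalized_infection_present(rec(b), idx))
  mk_cprd <- function(gap) {
    test_bundle("EMR_CPRD",
                events = rbind(ev_spec("p1", -50, "sepsis"),
                               ev_spec("p1", -50 + gap, "hospital_admission")))
  }
  expect_true(hospitalized_infection_present(rec(mk_cprd(5)), idx))
  expect_true(hospitalized_infection_present(rec(mk_cprd(-7)), idx))
  expect_false(hospitalized_infection_present(rec(mk_cprd(10)), idx))
})

test_that("claims meningitis needs repeat codes plus supporting evidence", {
  two_men <- ev_spec("p1", c(-30, -20), "meningitis")
  b <- test_bundle("CLAIMS_DOD", events = rbind(two_men,
                                                ev_spec("p1", -25, "dizziness")))
  expect_true(meningitis_dod_present(rec(b), idx))
  b <- test_bundle("CLAIMS_DOD", events = two_men,
                   rx = rx_spec("p1", -22, "amoxicillin"))
  expect_true(meningitis_dod_present(rec(b), idx))
  b <- test_bundle("CLAIMS_DOD", events = two_men)
  expect_false(meningitis_dod_present(rec(b), idx))
  b <- test_bundle("CLAIMS_DOD", events = ev_spec("p1", -30, "meningitis"))
  expect_false(meningitis_dod_present(rec(b), idx))
  b <- test_bundle("CLAIMS_DOD", ids = "p1")
  expect_false(meningitis_dod_present(rec(b), idx))
})

test_that("suicidal behaviors include overdose only in the EMR dialect", {
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", -100, "self_harm"))
  expect_true(suicidal_present(rec(b), idx))
  b <- test_bundle("EMR_CPRD", ids = "p1")
  expect_false(suicidal_present(rec(b), idx))
  bd <- test_bundle("CLAIMS_DOD", events = ev_spec("p1", -100, "overdose"))
  expect_false(suicidal_present(rec(bd), idx))
  bc <- test_bundle("EMR_CPRD", events = ev_spec("p1", -100, "overdose"))
  expect_true(suicidal_present(rec(bc), idx))
})

test_that("medication use counts prescriptions inside the closed year", {
  b <- test_bundle("CLAIMS_DOD", rx = rx_spec("p1", c(-300, -100, -10), "oxycodone"))
  u <- medication_use(rec(b), "opioids", idx)
  expect_true(u$present)
  expect_identical(u$n_rx, 3L)
  b <- test_bundle("CLAIMS_DOD", rx = rx_spec("p1", -366, "oxycodone"))
  u <- medication_use(rec(b), "opioids", idx)
  expect_false(u$present)
  expect_identical(u$n_rx, 0L)
  # n_issues are summed as prescription counts
  b <- test_bundle("CLAIMS_DOD", rx = rx_spec("p1", -30, "oxycodone", n = 4L))
  expect_identical(medication_use(rec(b), "opioids", idx)$n_rx, 4L)
})

test_that("anticonvulsants are attributed by epilepsy history", {
  b <- test_bundle("CLAIMS_DOD", events = ev_spec("p1", -730, "epilepsy"),
                   rx = rx_spec("p1", -30, "gabapentin"))
  expect_identical(attribute_anticonvulsants(rec(b), idx), "epilepsy_treatment")
  b <- test_bundle("CLAIMS_DOD", rx = rx_spec("p1", -30, "gabapentin"))
  expect_identical(attribute_anticonvulsants(rec(b), idx),
                   "ms_symptom_treatment")
  b <- test_bundle("CLAIMS_DOD", ids = "p1")
  expect_identical(attribute_anticonvulsants(rec(b), idx), "none")
})

test_that("covariates take the most recent value with half-open BMI bands", {
  b <- test_bundle("EMR_CPRD",
                   events = rbind(
                     ev_spec("p1", -900, "smoking_current"),
                     ev_spec("p1", -100, "smoking_never"),
                     ev_spec("p1", -200, "bmi_measurement", value = 24.9)))
  cov <- categorize_covariates(rec(b), idx)
  expect_identical(cov$smoking, "never")
  expect_identical(cov$bmi_band, "18.5-25")
  b <- test_bundle("EMR_CPRD",
                   events = ev_spec("p1", -10, "bmi_measurement", value = 30))
  expect_identical(categorize_covariates(rec(b), idx)$bmi_band, "30+")
  b <- test_bundle("EMR_CPRD", ids = "p1")
  cov <- categorize_covariates(rec(b), idx)
  expect_identical(cov$smoking, "unknown")
  expect_identical(cov$bmi_band, "unknown")
  expect_error(bmi_band(-3), "non-positive")
})

test_that("enlarging a look-back window never loses a positive", {
  withr::local_seed(17)
  for (i in 1:30) {
    d <- -sample(0:800, 1)
    b <- test_bundle("EMR_CPRD", events = ev_spec("p1", d, "uti"))
    r <- rec(b)
    short <- acute_window_present(r, "infection:urinary_kidney", idx,
                                  window_days = 180)
    long <- acute_window_present(r, "infection:urinary_kidney", idx,
                                 window_days = 800)
    expect_true(!short || long)
  }
})

test_that("the vectorized engine agrees with naive scans on random records", {
  withr::local_seed(99)
  concepts <- c("ms", "epilepsy", "depression", "fluoxetine", "uti",
                "cancer_primary", "cancer_history", "sepsis",
                "hospital_admission", "self_harm", "oxycodone", "gabapentin")
  cl <- default_codelist()
  for (i in 1:120) {
    dialect <- sample(c("CLAIMS_DOD", "EMR_CPRD"), 1)
    n_ev <- sample(0:12, 1)
    ev <- if (n_ev > 0) {
      ev_spec("p1", sample(-700:30, n_ev, replace = TRUE),
              sample(setdiff(concepts, c("fluoxetine", "oxycodone", "gabapentin")),
                     n_ev, replace = TRUE),
              setting = sample(c("inpatient", "outpatient"), n_ev,
                               replace = TRUE))
    }
    n_rx <- sample(0:5, 1)
    rx <- if (n_rx > 0) {
      rx_spec("p1", sample(-700:30, n_rx, replace = TRUE),
              sample(c("fluoxetine", "oxycodone", "gabapentin"), n_rx,
                     replace = TRUE))
    }
    b <- test_bundle(dialect, events = ev, rx = rx, ids = "p1")
    r <- rec(b)
    thr <- if (dialect == "CLAIMS_DOD") 5L else 1L
    expect_identical(chronic_present(r, "comorbidity:epilepsy", idx),
                     oracle_chronic(b, "p1", "epilepsy", idx, thr))
    expect_identical(acute_window_present(r, "infection:urinary_kidney", idx),
                     oracle_acute(b, "p1", "uti", idx, 365))
    expect_identical(
      treated_pair_present(r, "comorbidity:depression",
                           "medication:antidepressants", idx),
      oracle_pair(b, "p1", "depression", "fluoxetine", idx))
    if (dialect == "CLAIMS_DOD") {
      expect_identical(cancer_present(r, idx), oracle_cancer_dod(b, "p1", idx))
    }
    expect_identical(suicidal_present(r, idx),
                     oracle_acute(b, "p1", "self_harm", idx, Inf))
    rxr <- b$prescriptions
    n_op <- sum(rxr$n_issues[rxr$drug_concept == "oxycodone" &
                               rxr$rx_date >= idx - 365 & rxr$rx_date <= idx])
    expect_identical(medication_use(r, "opioids", idx)$n_rx, as.integer(n_op))
  }
})
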