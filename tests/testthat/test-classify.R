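classify_one <- function(bundle) {
  cls <- if (bundle$dialect == "CLAIMS_DOD") classify_dod(bundle)
         else classify_cprd(bundle)
  cls[1, ]
}

test_that("claims classifier reproduces the published rule examples", {
  # a typical probable case: many diagnoses, many DMT fills
  expect_identical(as.character(classify_one(count_record(45, 0, 30))$tier),
                   "PROBABLE")
  # diagnoses but no DMT at all: fails the entry gate
  expect_identical(as.character(classify_one(count_record(8, 0, 0))$tier),
                   "NON_CASE")
  # empty record
  expect_identical(as.character(classify_one(count_record(0, 0, 0))$tier),
                   "NON_CASE")
  # demyelinating codes only, with treatment
  expect_identical(as.character(classify_one(count_record(0, 3, 2))$tier),
                   "POSSIBLE_DEMYELINATING_ONLY")
  # low counts on both axes
  expect_identical(as.character(classify_one(count_record(3, 0, 2))$tier),
                   "POSSIBLE_LOW_COUNT")
  # boundary overlap: probable takes precedence over possible
  expect_identical(as.character(classify_one(count_record(10, 0, 5))$tier),
                   "PROBABLE")
})

test_that("claims classifier dispatches on dialect", {
  expect_error(classify_dod(count_record(2, 0, 2, dialect = "EMR_CPRD")),
               "CLAIMS_DOD")
  expect_error(classify_cprd(count_record(2, 0, 2)), "EMR_CPRD")
})

test_that("EMR classifier reproduces the published rule examples", {
  # two MS dates plus a symptom code
  b <- test_bundle("EMR_CPRD",
                   events = rbind(ev_spec("p1", c(1, 30), "ms"),
                                  ev_spec("p1", 10, "paresthesia")))
  expect_identical(as.character(classify_one(b)$tier), "PROBABLE")
  # one MS code, no support
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", 1, "ms"))
  expect_identical(as.character(classify_one(b)$tier), "UNLIKELY")
  # no MS codes
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", 1, "paresthesia"))
  expect_identical(as.character(classify_one(b)$tier), "NON_CASE")
  # two MS codes on the SAME date count as one distinct date
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", c(5, 5), "ms"))
  expect_identical(as.character(classify_one(b)$tier), "UNLIKELY")
  # one MS code with a symptomatic-treatment prescription
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", 1, "ms"),
                   rx = rx_spec("p1", 20, "baclofen"))
  expect_identical(as.character(classify_one(b)$tier),
                   "POSSIBLE_CPRD_SUPPORTED")
  # two MS dates, no support
  b <- test_bundle("EMR_CPRD", events = ev_spec("p1", c(1, 30), "ms"))
  expect_identical(as.character(classify_one(b)$tier),
                   "POSSIBLE_CPRD_UNSUPPORTED")
})

test_that("both classifiers agree with brute-force rule tables on a spot grid", {
  for (ms in 0:6) {
    for (demy in c(0L, 1L, 11L)) {
      for (dmt in c(0L, 1L, 5L, 10L, 11L)) {
        b <- count_record(ms, demy, dmt)
        expect_identical(as.character(classify_one(b)$tier),
                         oracle_dod_tier(ms, demy, dmt),
                         label = sprintf("dod ms=%d demy=%d dmt=%d",
                                         ms, demy, dmt))
      }
    }
    for (sup in c(TRUE, FALSE)) {
      b <- count_record(ms, 0, 0, dialect = "EMR_CPRD", support = sup)
      expect_identical(as.character(classify_one(b)$tier),
                       oracle_cprd_tier(ms, sup),
                       label = sprintf("cprd ms=%d support=%s", ms, sup))
    }
  }
})

test_that("adding evidence never demotes a probable claims case", {
  withr::local_seed(31)
  for (i in 1:25) {
    ms <- sample(0:14, 1); demy <- sample(0:14, 1); dmt <- sample(0:14, 1)
    if (oracle_dod_tier(ms, demy, dmt) != "PROBABLE") next
    more_ms <- classify_one(count_record(ms + 1, demy, dmt))
    more_dmt <- classify_one(count_record(ms, demy, dmt + 1))
    expect_identical(as.character(more_ms$tier), "PROBABLE")
    expect_identical(as.character(more_dmt$tier), "PROBABLE")
  }
})

test_that("exclusion rules follow the published three-branch definition", {
  # ALS at any time excludes regardless of evidence
  ev <- rbind(ev_spec("p1", seq_len(45), "ms"), ev_spec("p1", -3650, "als"))
  b <- test_bundle("CLAIMS_DOD", events = ev,
                   rx = rx_spec("p1", 100 + 1:30, "interferon_beta"))
  cls <- apply_exclusions(b, classify_dod(b))
  expect_true(cls$excluded[1])
  expect_identical(cls$exclusion_reason[1], "als_any_time")

  # EMR: one MS code, stroke 90 days after it
  b <- test_bundle("EMR_CPRD",
                   events = rbind(ev_spec("p1", 0, "ms"),
                                  ev_spec("p1", 90, "stroke")))
  cls <- apply_exclusions(b, classify_cprd(b))
  expect_true(cls$excluded[1])
  expect_identical(cls$exclusion_reason[1], "stroke_tia_near_ms")

  # stroke beyond 6 months after the MS code does not trigger rule 3
  b <- test_bundle("EMR_CPRD",
                   events = rbind(ev_spec("p1", 0, "ms"),
                                  ev_spec("p1", 184, "stroke")))
  expect_false(apply_exclusions(b, classify_cprd(b))$excluded[1])

  # claims: six distinct MS dates shields against the prior-TIA rule
  ev <- rbind(ev_spec("p1", 1:6, "ms"), ev_spec("p1", -500, "tia"))
  b <- test_bundle("CLAIMS_DOD", events = ev,
                   rx = rx_spec("p1", 10, "interferon_beta"))
  expect_false(apply_exclusions(b, classify_dod(b))$excluded[1])

  # alternate diagnosis with a single EMR MS code
  b <- test_bundle("EMR_CPRD",
                   events = rbind(ev_spec("p1", 0, "ms"),
                                  ev_spec("p1", -200, "other_neuro_alternate")))
  cls <- apply_exclusions(b, classify_cprd(b))
  expect_identical(cls$exclusion_reason[1], "alternate_dx_few_ms_codes")

  # nothing suspicious: not excluded
  b <- count_record(45, 0, 30)
  expect_false(apply_exclusions(b, classify_dod(b))$excluded[1])
})

test_that("incident filter requires one merged period covering the prior year", {
  mk <- function(start, end, extra = NULL) {
    en <- tibble::tibble(patient_id = "p1", start_date = day(start),
                         end_date = day(end))
    if (!is.null(extra)) en <- rbind(en, tibble::tibble(
      patient_id = "p1", start_date = day(extra[1]), end_date = day(extra[2])))
    b <- test_bundle("EMR_CPRD",
                     events = rbind(ev_spec("p1", c(0, 40), "ms"),
                                    ev_spec("p1", 5, "paresthesia")),
                     enrollment = en)
    incident_filter(b, classify_cprd(b))$incident[1]
  }
  expect_false(mk(-100, 400))         # only 100 days of run-in
  expect_true(mk(-365, 400))          # exactly one year: boundary included
  expect_false(mk(-400, -200, c(-100, 400))) # gap inside the look-back year
  expect_true(mk(-400, -150, c(-151, 400)))  # abutting periods merge
})

test_that("cohort membership excludes unlikely, excluded and prevalent cases", {
  ev <- rbind(
    ev_spec("case1", c(0, 30), "ms"), ev_spec("case1", 3, "paresthesia"),
    ev_spec("unl", 0, "ms"),
    ev_spec("exc", c(0, 20), "ms"), ev_spec("exc", 2, "paresthesia"),
    ev_spec("exc", -100, "als"),
    ev_spec("prev", c(0, 10), "ms"), ev_spec("prev", 1, "paresthesia")
  )
  en <- tibble::tibble(
    patient_id = c("case1", "unl", "exc", "prev", "ctrl"),
    start_date = day(c(-4000, -4000, -4000, -100, -4000)),
    end_date = day(4000)
  )
  b <- test_bundle("EMR_CPRD", events = ev, ids = "ctrl", enrollment = en)
  cohort <- build_ms_cohort(b)
  expect_identical(cohort$patient_id, "case1")
  expect_identical(cohort$entry_date, day(0))
  # an MS-free population yields an empty cohort
  b0 <- test_bundle("EMR_CPRD", ids = c("a", "b"))
  expect_identical(nrow(build_ms_cohort(b0)), 0L)
})

test_that("classification is independent of record ordering", {
  ev <- rbind(ev_spec("p1", c(3, 1, 2, 1), "ms"),
              ev_spec("p1", 8, "paresthesia"))
  b1 <- test_bundle("EMR_CPRD", events = ev)
  b2 <- test_bundle("EMR_CPRD", events = ev[rev(seq_len(nrow(ev))), ])
  expect_identical(classify_cprd(b1)$tier, classify_cprd(b2)$tier)
  expect_identical(classify_cprd(b1)$n_ms_dx_dates,
                   classify_cprd(b2)$n_ms_dx_dates)
})
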