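# compact constructors for hand-built test records -----------------------
# dates are integer day offsets from a fixed base date

BASE_DATE <- as.Date("2010-01-01")

day <- function(n) BASE_DATE + n

# events/rx given as data.frames with (id, day, concept [, setting | n]).
# every referenced patient gets sex F, one geography unit and enrollment
# covering day -4000 .. 4000 unless overridden.
test_bundle <- function(dialect = "CLAIMS_DOD", events = NULL, rx = NULL,
                        ids = NULL, enrollment = NULL, sex = "F",
                        geography = "g1", birth = as.Date("1970-06-15")) {
  ids <- unique(c(ids, events$id, rx$id)) %||% "p1"
  if (length(ids) == 0) ids <- "p1"
  patients <- tibble::tibble(
    patient_id = ids, sex = sex, birth_date = birth,
    geography = geography, dialect = dialect
  )
  if (is.null(enrollment)) {
    enrollment <- tibble::tibble(patient_id = ids, start_date = day(-4000),
                                 end_date = day(4000))
  }
  ev <- if (is.null(events) || nrow(events) == 0) {
    tibble::tibble(patient_id = character(0),
                   event_date = as.Date(character(0)),
                   concept = character(0), setting = character(0))
  } else {
    tibble::tibble(patient_id = events$id, event_date = day(events$day),
                   concept = events$concept,
                   setting = events$setting %||% "outpatient",
                   value = events$value %||% NA_real_)
  }
  rxt <- if (is.null(rx) || nrow(rx) == 0) {
    tibble::tibble(patient_id = character(0), rx_date = as.Date(character(0)),
                   drug_concept = character(0), n_issues = integer(0))
  } else {
    tibble::tibble(patient_id = rx$id, rx_date = day(rx$day),
                   drug_concept = rx$concept, n_issues = rx$n %||% 1L)
  }
  ms_bundle(patients, enrollment, ev, rxt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ev_spec <- function(id, day, concept, setting = "outpatient",
                    value = NA_real_) {
  data.frame(id = id, day = day, concept = concept, setting = setting,
             value = value, stringsAsFactors = FALSE)
}

rx_spec <- function(id, day, concept, n = 1L) {
  data.frame(id = id, day = day, concept = concept, n = as.integer(n),
             stringsAsFactors = FALSE)
}

# a synthetic DOD record with the given distinct-date counts: MS diagnoses,
# demyelinating diagnoses (on disjoint dates) and DMT prescription rows
count_record <- function(n_ms, n_demy, n_dmt, dialect = "CLAIMS_DOD",
                         support = FALSE, id = "p1") {
  ev <- NULL
  if (n_ms > 0) ev <- rbind(ev, ev_spec(id, seq_len(n_ms), "ms"))
  if (n_demy > 0) {
    ev <- rbind(ev, ev_spec(id, 100 + seq_len(n_demy), "demyelinating_disease"))
  }
  if (support) ev <- rbind(ev, ev_spec(id, 50, "paresthesia"))
  rx <- if (n_dmt > 0) rx_spec(id, 200 + seq_len(n_dmt), "interferon_beta")
  test_bundle(dialect, events = ev, rx = rx, ids = id)
}
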