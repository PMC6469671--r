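#' Outcome definitions for the comparison tables
#'
#' Declarative outcome set mirroring the study tables: MS symptom history
#' (any time before entry), chronic comorbidities (at least one code in the
#' EMR dialect, at least five distinct-date codes in the claims dialect),
#' treated depression/hypertension/diabetes (diagnosis and prescription
#' within 90 days of each other), the dialect-specific cancer rules,
#' suicidal behaviors, acute infections in the year before entry,
#' hospitalized infections, the claims meningitis rule, and
#' concomitant-medication use in the year before entry with anticonvulsants
#' attributed to epilepsy or MS-symptom treatment.
#'
#' @return a tibble with columns
#'   `name, kind, category, rx_category, window_days, table, label`.
#' @export
default_outcomes <- function() {
  sym <- function(name, concept, label) {
    tibble::tibble(name = name, kind = "ACUTE_WINDOW",
                   category = paste0("concept:", concept),
                   rx_category = NA_character_, window_days = Inf,
                   table = 3L, label = label)
  }
  dplyr::bind_rows(
    sym("optic_neuritis", "optic_neuritis", "Optic neuritis"),
    sym("paresis", "paresis", "Paresis, plegia, paralysis, muscle weakness"),
    sym("spasticity_ataxia", "spasticity_ataxia",
        "Spasms, lack of coordination, abnormality of gait"),
    sym("paresthesia", "paresthesia", "Disturbance of skin sensation"),
    sym("dizziness", "dizziness", "Dizziness and giddiness"),
    sym("fatigue", "fatigue", "Malaise and fatigue"),
    sym("vision_symptoms", "vision_symptoms", "Vision symptoms"),
    sym("bladder_symptoms", "bladder_symptoms", "Bladder symptoms"),
    tibble::tribble(
      ~name, ~kind, ~category, ~rx_category, ~window_days, ~table, ~label,
      "treated_depression", "TREATED_PAIR", "comorbidity:depression",
        "medication:antidepressants", Inf, 4L, "Treated depression",
      "treated_hypertension", "TREATED_PAIR", "comorbidity:hypertension",
        "medication:antihypertensives", Inf, 4L, "Treated hypertension",
      "treated_diabetes", "TREATED_PAIR", "comorbidity:diabetes",
        "medication:antidiabetics", Inf, 4L, "Treated diabetes",
      "epilepsy", "CHRONIC", "comorbidity:epilepsy", NA, Inf, 4L, "Epilepsy",
      "asthma_copd", "CHRONIC", "comorbidity:asthma_copd", NA, Inf, 4L,
        "Asthma or COPD",
      "dyslipidemia", "CHRONIC", "comorbidity:dyslipidemia", NA, Inf, 4L,
        "Dyslipidemia",
      "fracture", "CHRONIC", "comorbidity:fracture", NA, Inf, 4L, "Fracture",
      "cancer", "CANCER", "comorbidity:cancer", NA, Inf, 4L, "Cancer",
      "suicidal_behaviors", "SUICIDAL", "suicidal_behavior", NA, Inf, 4L,
        "Suicidal behaviors",
      "hospitalized_infections", "HOSPITALIZED_INFECTION", "infection:",
        NA, 365, 5L, "Hospitalized infections",
      "urinary_kidney_infections", "ACUTE_WINDOW", "infection:urinary_kidney",
        NA, 365, 5L, "Urinary and kidney infections",
      "respiratory_throat_infections", "ACUTE_WINDOW",
        "infection:respiratory_throat", NA, 365, 5L,
        "Respiratory and throat infections",
      "skin_infections", "ACUTE_WINDOW", "infection:skin", NA, 365, 5L,
        "Skin infections",
      "eye_ear_infections", "ACUTE_WINDOW", "infection:eye_ear", NA, 365, 5L,
        "Eye and ear infections",
      "viral_infections", "ACUTE_WINDOW", "infection:viral", NA, 365, 5L,
        "Viral infectious diseases",
      "meningitis_encephalitis", "MENINGITIS", "infection:meningitis", NA,
        365, 5L, "Meningitis and encephalitis",
      "spasticity_treatments", "MEDICATION_USE", "medication:spasticity", NA,
        365, 6L, "Spasticity treatments",
      "anticonvulsants_no_epilepsy", "MEDICATION_USE",
        "medication:anticonvulsants", NA, 365, 6L,
        "Anticonvulsants with no epilepsy diagnoses",
      "anticonvulsants_with_epilepsy", "MEDICATION_USE",
        "medication:anticonvulsants", NA, 365, 6L,
        "Anticonvulsants with at least one epilepsy diagnosis",
      "steroids", "MEDICATION_USE", "medication:steroids", NA, 365, 6L,
        "Steroids",
      "neuropathic_pain_treatments", "MEDICATION_USE",
        "medication:neuropathic_pain", NA, 365, 6L,
        "Neuropathic pain treatments",
      "opioids", "MEDICATION_USE", "medication:opioids", NA, 365, 6L,
        "Opioids",
      "fatigue_treatments", "MEDICATION_USE", "medication:fatigue", NA, 365,
        6L, "Fatigue treatments",
      "antidepressants", "MEDICATION_USE", "medication:antidepressants", NA,
        365, 6L, "Antidepressants",
      "antibiotics", "MEDICATION_USE", "medication:antibiotics", NA, 365, 6L,
        "Antibiotics",
      "smoking", "CATEGORICAL_COVARIATE", "covariate:smoking", NA, Inf, 2L,
        "Smoking",
      "bmi_band", "CATEGORICAL_COVARIATE", "covariate:bmi", NA, Inf, 2L,
        "BMI"
    )
  )
}

# resolve an outcome category spec ("concept:x", "infection:" prefix, or a
# plain category) into concept identifiers
resolve_concepts <- function(codelist, category) {
  if (startsWith(category, "concept:")) {
    sub("^concept:", "", category)
  } else if (endsWith(category, ":")) {
    concepts_in(codelist, category, prefix = TRUE)
  } else {
    concepts_in(codelist, category)
  }
}

#' Classify a BMI value into the reporting bands
#'
#' Bands are half-open: underweight `< 18.5`, normal `[18.5, 25)`,
#' overweight `[25, 30)`, obese `>= 30`.
#'
#' @param value numeric BMI in kg/m2.
#' @return character band label.
#' @export
bmi_band <- function(value) {
  if (any(!is.na(value) & value <= 0)) {
    stop("non-positive BMI value", call. = FALSE)
  }
  cut(value, c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("<18.5", "18.5-25", "25-30", "30+")) |>
    as.character()
}

## ---- vectorized kernels -------------------------------------------------
## each takes events/prescriptions pre-joined with the analysis frame
## (columns ... , index_date) and returns patient ids testing positive

k_chronic <- function(evj, codelist, dialect, category) {
  threshold <- if (dialect == "CLAIMS_DOD") 5L else 1L
  keep <- resolve_concepts(codelist, category)
  x <- evj[evj$concept %in% keep & evj$event_date <= evj$index_date, ]
  cnt <- dplyr::summarise(dplyr::group_by(x, .data$patient_id),
                          n = length(unique(.data$event_date)),
                          .groups = "drop")
  cnt$patient_id[cnt$n >= threshold]
}

k_acute <- function(evj, codelist, category, window_days) {
  keep <- resolve_concepts(codelist, category)
  x <- evj[evj$concept %in% keep & evj$event_date <= evj$index_date, ]
  if (is.finite(window_days)) {
    x <- x[x$event_date >= x$index_date - window_days, ]
  }
  unique(x$patient_id)
}

k_treated_pair <- function(evj, rxj, codelist, dx_category, rx_category) {
  dxc <- resolve_concepts(codelist, dx_category)
  rxc <- resolve_concepts(codelist, rx_category)
  dx <- evj[evj$concept %in% dxc & evj$event_date <= evj$index_date,
            c("patient_id", "event_date")]
  rx <- rxj[rxj$drug_concept %in% rxc & rxj$rx_date <= rxj$index_date,
            c("patient_id", "rx_date")]
  pairs <- dplyr::inner_join(dx, rx, by = "patient_id",
                             relationship = "many-to-many")
  unique(pairs$patient_id[abs(as.numeric(pairs$event_date - pairs$rx_date)) <= 90])
}

# any >= 5 codes spanning <= 183 days, as a sliding distinct-date window
dates_cluster <- function(d, k = 5L, span = DAYS_HALF_YEAR) {
  d <- sort(unique(as.numeric(d)))
  n <- length(d)
  n >= k && any(d[seq_len(n - k + 1) + k - 1] - d[seq_len(n - k + 1)] <= span)
}

k_cancer <- function(evj, codelist, dialect) {
  cc <- resolve_concepts(codelist, "comorbidity:cancer")
  hc <- resolve_concepts(codelist, "comorbidity:cancer_history")
  x <- evj[evj$concept %in% c(cc, hc) & evj$event_date <= evj$index_date, ]
  if (dialect == "EMR_CPRD") return(unique(x$patient_id))
  hist_ids <- unique(x$patient_id[x$concept %in% hc])
  prim <- x[x$concept %in% cc, ]
  per <- split(prim$event_date, prim$patient_id)
  many <- names(per)[vapply(per, function(d) length(d) >= 10 || dates_cluster(d),
                            logical(1))]
  unique(c(hist_ids, many))
}

k_hospitalized_infection <- function(evj, codelist, dialect,
                                     window_days = DAYS_YEAR) {
  inf <- resolve_concepts(codelist, "infection:")
  x <- evj[evj$concept %in% inf &
             evj$event_date <= evj$index_date &
             evj$event_date >= evj$index_date - window_days, ]
  if (dialect == "CLAIMS_DOD") {
    return(unique(x$patient_id[x$setting == "inpatient"]))
  }
  mk <- resolve_concepts(codelist, "hospitalization_marker")
  m <- evj[evj$concept %in% mk &
             evj$event_date <= evj$index_date &
             evj$event_date >= evj$index_date - window_days,
           c("patient_id", "event_date")]
  names(m)[2] <- "marker_date"
  pairs <- dplyr::inner_join(x[, c("patient_id", "event_date")], m,
                             by = "patient_id", relationship = "many-to-many")
  unique(pairs$patient_id[
    abs(as.numeric(pairs$event_date - pairs$marker_date)) <= DAYS_WEEK])
}

k_meningitis <- function(evj, rxj, codelist, dialect, window_days = DAYS_YEAR,
                         n_dates = 2L) {
  men <- resolve_concepts(codelist, "infection:meningitis")
  x <- evj[evj$concept %in% men &
             evj$event_date <= evj$index_date &
             evj$event_date >= evj$index_date - window_days, ]
  if (dialect == "EMR_CPRD") return(unique(x$patient_id))
  cnt <- dplyr::summarise(dplyr::group_by(x, .data$patient_id),
                          n = length(unique(.data$event_date)),
                          .groups = "drop")
  multi <- cnt$patient_id[cnt$n >= n_dates]
  sup_cat <- c("symptomatic_treatment", "ms_symptom", "medication:antibiotics")
  sup_concepts <- concepts_in(codelist, sup_cat)
  sup_ids <- unique(c(
    evj$patient_id[evj$concept %in% sup_concepts &
                     evj$event_date <= evj$index_date &
                     evj$event_date >= evj$index_date - window_days],
    rxj$patient_id[rxj$drug_concept %in% sup_concepts &
                     rxj$rx_date <= rxj$index_date &
                     rxj$rx_date >= rxj$index_date - window_days]
  ))
  intersect(multi, sup_ids)
}

k_suicidal <- function(evj, codelist, dialect) {
  keep <- intersect(resolve_concepts(codelist, "suicidal_behavior"),
                    active_concepts(codelist, dialect))
  unique(evj$patient_id[evj$concept %in% keep &
                          evj$event_date <= evj$index_date])
}

k_medication_counts <- function(rxj, codelist, category,
                                window_days = DAYS_YEAR) {
  keep <- resolve_concepts(codelist, category)
  x <- rxj[rxj$drug_concept %in% keep &
             rxj$rx_date <= rxj$index_date &
             rxj$rx_date >= rxj$index_date - window_days, ]
  dplyr::summarise(dplyr::group_by(x, .data$patient_id),
                   n_rx = sum(.data$n_issues), .groups = "drop")
}

# patients with >= 1 epilepsy diagnosis code on or before index
k_epilepsy_ever <- function(evj, codelist) {
  keep <- resolve_concepts(codelist, "comorbidity:epilepsy")
  unique(evj$patient_id[evj$concept %in% keep &
                          evj$event_date <= evj$index_date])
}

k_latest_covariate <- function(evj, codelist, category) {
  keep <- resolve_concepts(codelist, category)
  x <- evj[evj$concept %in% keep & evj$event_date <= evj$index_date, ]
  x <- x[order(x$patient_id, x$event_date), ]
  x[!duplicated(x$patient_id, fromLast = TRUE),
    c("patient_id", "concept", "value")]
}

## ---- engine -------------------------------------------------------------

join_frame <- function(tab, frame) {
  dplyr::inner_join(tab, frame[, c("patient_id", "index_date")],
                    by = "patient_id", relationship = "many-to-many")
}

#' Evaluate every outcome for each cohort member at the index date
#'
#' @param bundle an [ms_bundle()].
#' @param frame analysis frame from [analysis_frame()] (columns
#'   `patient_id, arm, index_date`); controls are anchored on their case's
#'   index date.
#' @param outcomes outcome definitions (default [default_outcomes()]).
#' @return long tibble `patient_id, arm, outcome, present, n_rx,
#'   category_value` with one row per member per outcome.
#' @export
ascertain_outcomes <- function(bundle, frame, outcomes = default_outcomes()) {
  cl <- bundle$codelist
  dialect <- bundle$dialect
  evj <- join_frame(bundle$events, frame)
  rxj <- join_frame(bundle$prescriptions, frame)
  epi_ever <- k_epilepsy_ever(evj, cl)

  res <- vector("list", nrow(outcomes))
  for (r in seq_len(nrow(outcomes))) {
    o <- outcomes[r, ]
    base <- tibble::tibble(patient_id = frame$patient_id, arm = frame$arm,
                           outcome = o$name, present = FALSE,
                           n_rx = 0L, category_value = NA_character_)
    if (o$kind == "CATEGORICAL_COVARIATE") {
      latest <- k_latest_covariate(evj, cl, o$category)
      i <- match(base$patient_id, latest$patient_id)
      if (o$name == "smoking") {
        status <- sub("^smoking_", "", latest$concept[i])
        base$category_value <- ifelse(is.na(i), "unknown", status)
      } else {
        base$category_value <- ifelse(is.na(i), "unknown",
                                      bmi_band(latest$value[i]))
      }
      base$present <- base$category_value != "unknown"
      res[[r]] <- base
      next
    }
    if (o$kind == "MEDICATION_USE") {
      cnt <- k_medication_counts(rxj, cl, o$category, o$window_days)
      if (o$name == "anticonvulsants_no_epilepsy") {
        cnt <- cnt[!cnt$patient_id %in% epi_ever, ]
      } else if (o$name == "anticonvulsants_with_epilepsy") {
        cnt <- cnt[cnt$patient_id %in% epi_ever, ]
      }
      i <- match(base$patient_id, cnt$patient_id)
      base$n_rx <- ifelse(is.na(i), 0L, cnt$n_rx[i])
      base$present <- base$n_rx >= 1
      res[[r]] <- base
      next
    }
    ids <- switch(
      o$kind,
      CHRONIC = k_chronic(evj, cl, dialect, o$category),
      ACUTE_WINDOW = k_acute(evj, cl, o$category, o$window_days),
      TREATED_PAIR = k_treated_pair(evj, rxj, cl, o$category, o$rx_category),
      CANCER = k_cancer(evj, cl, dialect),
      HOSPITALIZED_INFECTION = k_hospitalized_infection(evj, cl, dialect,
                                                        o$window_days),
      MENINGITIS = k_meningitis(evj, rxj, cl, dialect, o$window_days),
      SUICIDAL = k_suicidal(evj, cl, dialect),
      stop("unknown outcome kind: ", o$kind, call. = FALSE)
    )
    base$present <- base$patient_id %in% ids
    res[[r]] <- base
  }
  dplyr::bind_rows(res)
}

## ---- single-record primitives ------------------------------------------

one_frame <- function(record, index_date) {
  tibble::tibble(patient_id = record$patients$patient_id[[1]], arm = "ms",
                 index_date = as.Date(index_date))
}

#' Single-record outcome primitives
#'
#' Per-record forms of the ascertainment rules, convenient for inspection
#' and testing; each takes a one-patient record (see [patient_record()]) and
#' an index date and applies exactly the engine's rule.
#'
#' @param record a single-patient [ms_bundle()].
#' @param index_date the index (cohort entry) date.
#' @param category,dx_category,rx_category concept category names.
#' @param window_days look-back window length in days (closed interval).
#' @param med_class medication class name (e.g. `"opioids"`), resolved to
#'   the `medication:<class>` category.
#' @param dialect record dialect; defaults to the record's own.
#' @name outcome-primitives
NULL

#' @rdname outcome-primitives
#' @export
chronic_present <- function(record, category, index_date,
                            dialect = record$dialect) {
  f <- one_frame(record, index_date)
  f$patient_id %in% k_chronic(join_frame(record$events, f), record$codelist,
                              dialect, category)
}

#' @rdname outcome-primitives
#' @export
treated_pair_present <- function(record, dx_category, rx_category, index_date) {
  f <- one_frame(record, index_date)
  f$patient_id %in% k_treated_pair(join_frame(record$events, f),
                                   join_frame(record$prescriptions, f),
                                   record$codelist, dx_category, rx_category)
}

#' @rdname outcome-primitives
#' @export
cancer_present <- function(record, index_date, dialect = record$dialect) {
  f <- one_frame(record, index_date)
  f$patient_id %in% k_cancer(join_frame(record$events, f), record$codelist,
                             dialect)
}

#' @rdname outcome-primitives
#' @export
acute_window_present <- function(record, category, index_date,
                                 window_days = 365) {
  f <- one_frame(record, index_date)
  f$patient_id %in% k_acute(join_frame(record$events, f), record$codelist,
                            category, window_days)
}

#' @rdname outcome-primitives
#' @export
hospitalized_infection_present <- function(record, index_date,
                                           dialect = record$dialect) {
  f <- one_frame(record, index_date)
  f$patient_id %in% k_hospitalized_infection(join_frame(record$events, f),
                                             record$codelist, dialect)
}

#' @rdname outcome-primitives
#' @export
meningitis_dod_present <- function(record, index_date) {
  if (!identical(record$dialect, "CLAIMS_DOD")) {
    stop("meningitis_dod_present() requires a CLAIMS_DOD record",
         call. = FALSE)
  }
  f <- one_frame(record, index_date)
  f$patient_id %in% k_meningitis(join_frame(record$events, f),
                                 join_frame(record$prescriptions, f),
                                 record$codelist, "CLAIMS_DOD")
}

#' @rdname outcome-primitives
#' @export
suicidal_present <- function(record, index_date, dialect = record$dialect) {
  f <- one_frame(record, index_date)
  f$patient_id %in% k_suicidal(join_frame(record$events, f), record$codelist,
                               dialect)
}

#' @rdname outcome-primitives
#' @export
medication_use <- function(record, med_class, index_date) {
  f <- one_frame(record, index_date)
  cnt <- k_medication_counts(join_frame(record$prescriptions, f),
                             record$codelist, paste0("medication:", med_class))
  n <- if (nrow(cnt) == 0) 0L else cnt$n_rx[[1]]
  list(present = n >= 1, n_rx = as.integer(n))
}

#' @rdname outcome-primitives
#' @export
attribute_anticonvulsants <- function(record, index_date) {
  use <- medication_use(record, "anticonvulsants", index_date)
  if (!use$present) return("none")
  f <- one_frame(record, index_date)
  epi <- k_epilepsy_ever(join_frame(record$events, f), record$codelist)
  if (f$patient_id %in% epi) "epilepsy_treatment" else "ms_symptom_treatment"
}

#' @rdname outcome-primitives
#' @export
categorize_covariates <- function(record, index_date) {
  f <- one_frame(record, index_date)
  evj <- join_frame(record$events, f)
  smoking <- k_latest_covariate(evj, record$codelist, "covariate:smoking")
  bmi <- k_latest_covariate(evj, record$codelist, "covariate:bmi")
  list(
    smoking = if (nrow(smoking) == 0) "unknown"
              else sub("^smoking_", "", smoking$concept[[1]]),
    bmi_band = if (nrow(bmi) == 0) "unknown" else bmi_band(bmi$value[[1]])
  )
}
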