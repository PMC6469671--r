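#' Tiered MS case classification
#'
#' Two database-specific algorithms assign each patient a certainty tier.
#'
#' **Claims (DOD) algorithm** — entry gate: at least one MS or demyelinating
#' diagnosis *and* at least one DMT/dalfampridine prescription. `PROBABLE`:
#' at least ten MS-or-demyelinating diagnoses on different dates with at
#' least five DMT prescriptions, or at least five MS diagnoses on different
#' dates with at least ten DMT prescriptions. `POSSIBLE_DEMYELINATING_ONLY`:
#' demyelinating codes without any MS code, plus DMT.
#' `POSSIBLE_LOW_COUNT`: one to ten MS diagnosis dates and one to ten DMT
#' prescriptions. `PROBABLE` takes precedence over the possible tiers.
#'
#' **EMR (CPRD) algorithm** — `PROBABLE`: two or more MS diagnosis dates plus
#' supporting treatment and/or symptom codes. `POSSIBLE_CPRD_SUPPORTED`: at
#' least one MS diagnosis with support, short of probable.
#' `POSSIBLE_CPRD_UNSUPPORTED`: two or more MS diagnosis dates with no
#' support. `UNLIKELY`: a single MS diagnosis date and no support (reported
#' but never a cohort member). All MS/demyelinating thresholds count
#' distinct dates; DMT thresholds count prescription rows (sum of issues).
#'
#' @param bundle an [ms_bundle()] (one patient via [patient_record()], or a
#'   whole population — one classification row is returned per patient).
#' @return a tibble with columns `patient_id, tier, first_ms_date,
#'   n_ms_dx_dates, n_demyelinating_dx_dates, n_dmt_rx, has_support,
#'   excluded, exclusion_reason, incident`.
#' @name case-classification
NULL

TIERS <- c("PROBABLE", "POSSIBLE_DEMYELINATING_ONLY", "POSSIBLE_LOW_COUNT",
           "POSSIBLE_CPRD_SUPPORTED", "POSSIBLE_CPRD_UNSUPPORTED",
           "UNLIKELY", "NON_CASE")

# categories counting as CPRD supporting evidence (symptoms, symptomatic
# treatments, and drug classes used for MS symptoms)
CPRD_SUPPORT_CATEGORIES <- c("ms_symptom", "symptomatic_treatment",
                             "medication:spasticity",
                             "medication:neuropathic_pain",
                             "medication:fatigue")

safe_min_date <- function(x) if (length(x) == 0) as.Date(NA) else min(x)

# per-patient evidence counts shared by both classifiers
classification_counts <- function(bundle) {
  cl <- bundle$codelist
  ev <- bundle$events
  ev$category <- category_of(cl, ev$concept)
  rx <- bundle$prescriptions
  rx$category <- category_of(cl, rx$drug_concept)

  msdemy <- ev[ev$category %in% c("ms_diagnosis", "demyelinating_disease"), ]
  by_pat <- dplyr::group_by(msdemy, .data$patient_id)
  dx <- dplyr::summarise(
    by_pat,
    n_ms_dx_dates = length(unique(.data$event_date[.data$category == "ms_diagnosis"])),
    n_demyelinating_dx_dates =
      length(unique(.data$event_date[.data$category == "demyelinating_disease"])),
    n_msdemy_dates = length(unique(.data$event_date)),
    first_ms = safe_min_date(.data$event_date[.data$category == "ms_diagnosis"]),
    first_demy =
      safe_min_date(.data$event_date[.data$category == "demyelinating_disease"]),
    .groups = "drop"
  )
  dmt <- rx[rx$category == "dmt_or_dalfampridine", ] |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_dmt_rx = sum(.data$n_issues), .groups = "drop")
  sup_ids <- unique(c(
    ev$patient_id[ev$category %in% CPRD_SUPPORT_CATEGORIES],
    rx$patient_id[rx$category %in% CPRD_SUPPORT_CATEGORIES]
  ))
  excl <- ev[startsWith(ev$category, "exclusion:"), ] |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      has_als = any(.data$category == "exclusion:als"),
      has_alternate = any(.data$category == "exclusion:alternate"),
      first_stroke_tia = safe_min_date(
        .data$event_date[.data$category %in%
                           c("exclusion:stroke", "exclusion:tia")]),
      .groups = "drop"
    )

  out <- tibble::tibble(patient_id = bundle$patients$patient_id) |>
    dplyr::left_join(dx, by = "patient_id") |>
    dplyr::left_join(dmt, by = "patient_id") |>
    dplyr::left_join(excl, by = "patient_id")
  out$n_ms_dx_dates[is.na(out$n_ms_dx_dates)] <- 0L
  out$n_demyelinating_dx_dates[is.na(out$n_demyelinating_dx_dates)] <- 0L
  out$n_msdemy_dates[is.na(out$n_msdemy_dates)] <- 0L
  out$n_dmt_rx[is.na(out$n_dmt_rx)] <- 0L
  out$has_als[is.na(out$has_als)] <- FALSE
  out$has_alternate[is.na(out$has_alternate)] <- FALSE
  out$has_support <- out$patient_id %in% sup_ids
  out
}

finish_classification <- function(cnt, tier, first_ms_date) {
  out <- tibble::tibble(
    patient_id = cnt$patient_id,
    tier = factor(tier, levels = TIERS),
    first_ms_date = first_ms_date,
    n_ms_dx_dates = cnt$n_ms_dx_dates,
    n_demyelinating_dx_dates = cnt$n_demyelinating_dx_dates,
    n_dmt_rx = cnt$n_dmt_rx,
    has_support = cnt$has_support,
    excluded = FALSE,
    exclusion_reason = "none",
    incident = NA
  )
  attr(out, "counts") <- cnt
  out
}

#' @rdname case-classification
#' @export
classify_dod <- function(bundle) {
  if (!identical(bundle$dialect, "CLAIMS_DOD")) {
    stop("classify_dod() requires a CLAIMS_DOD bundle (got ",
         bundle$dialect, ")", call. = FALSE)
  }
  cnt <- classification_counts(bundle)
  gate <- cnt$n_msdemy_dates >= 1 & cnt$n_dmt_rx >= 1
  probable <- gate &
    ((cnt$n_msdemy_dates >= 10 & cnt$n_dmt_rx >= 5) |
       (cnt$n_ms_dx_dates >= 5 & cnt$n_dmt_rx >= 10))
  poss_demy <- gate & !probable &
    cnt$n_demyelinating_dx_dates >= 1 & cnt$n_ms_dx_dates == 0
  poss_low <- gate & !probable & !poss_demy &
    cnt$n_ms_dx_dates >= 1 & cnt$n_ms_dx_dates <= 10 &
    cnt$n_dmt_rx >= 1 & cnt$n_dmt_rx <= 10
  tier <- rep("NON_CASE", nrow(cnt))
  tier[poss_low] <- "POSSIBLE_LOW_COUNT"
  tier[poss_demy] <- "POSSIBLE_DEMYELINATING_ONLY"
  tier[probable] <- "PROBABLE"
  # cohort entry anchors on the first MS code; the demyelinating-only tier
  # has none by definition, so its first demyelinating code is used
  first_ms <- cnt$first_ms
  use_demy <- is.na(first_ms) & tier == "POSSIBLE_DEMYELINATING_ONLY"
  first_ms[use_demy] <- cnt$first_demy[use_demy]
  finish_classification(cnt, tier, first_ms)
}

#' @rdname case-classification
#' @export
classify_cprd <- function(bundle) {
  if (!identical(bundle$dialect, "EMR_CPRD")) {
    stop("classify_cprd() requires an EMR_CPRD bundle (got ",
         bundle$dialect, ")", call. = FALSE)
  }
  cnt <- classification_counts(bundle)
  nms <- cnt$n_ms_dx_dates
  sup <- cnt$has_support
  tier <- rep("NON_CASE", nrow(cnt))
  tier[nms == 1 & !sup] <- "UNLIKELY"
  tier[nms >= 2 & !sup] <- "POSSIBLE_CPRD_UNSUPPORTED"
  tier[nms == 1 & sup] <- "POSSIBLE_CPRD_SUPPORTED"
  tier[nms >= 2 & sup] <- "PROBABLE"
  finish_classification(cnt, tier, cnt$first_ms)
}

#' Apply the shared exclusion rules
#'
#' Cases are excluded when (1) ALS is coded at any time in the record, or
#' (2) an alternate diagnosis is present and few MS codes exist (exactly one
#' distinct MS date in the EMR dialect; fewer than five in the claims
#' dialect), or (3) the same few-MS-codes condition holds and a stroke or
#' TIA code is dated any time prior to, or up to 6 months (183 days,
#' inclusive) after, the first MS code. Reasons are assigned in that order.
#'
#' @param bundle the [ms_bundle()] the classification came from.
#' @param cls a classification tibble from [classify_dod()] /
#'   [classify_cprd()].
#' @return `cls` with `excluded` and `exclusion_reason` filled in.
#' @export
apply_exclusions <- function(bundle, cls) {
  cnt <- attr(cls, "counts") %||% classification_counts(bundle)
  cnt <- cnt[match(cls$patient_id, cnt$patient_id), ]
  few_ms <- if (bundle$dialect == "CLAIMS_DOD") {
    cls$n_ms_dx_dates < 5
  } else {
    cls$n_ms_dx_dates == 1
  }
  stroke_near <- !is.na(cnt$first_stroke_tia) & !is.na(cls$first_ms_date) &
    cnt$first_stroke_tia <= cls$first_ms_date + DAYS_HALF_YEAR
  reason <- rep("none", nrow(cls))
  reason[few_ms & stroke_near] <- "stroke_tia_near_ms"
  reason[cnt$has_alternate & few_ms] <- "alternate_dx_few_ms_codes"
  reason[cnt$has_als] <- "als_any_time"
  cls$exclusion_reason <- reason
  cls$excluded <- reason != "none"
  cls
}

#' Apply the incident-case filter
#'
#' A case is incident when a single merged enrollment period covers the full
#' closed year before the first MS code, i.e. `[first_ms_date - 365,
#' first_ms_date]`.
#'
#' @inheritParams apply_exclusions
#' @return `cls` with `incident` filled in (`NA` when no first MS date).
#' @export
incident_filter <- function(bundle, cls) {
  en <- bundle$enrollment
  need <- cls[!is.na(cls$first_ms_date), c("patient_id", "first_ms_date")]
  cov <- dplyr::inner_join(en, need, by = "patient_id",
                           relationship = "many-to-many") |>
    dplyr::filter(.data$start_date <= .data$first_ms_date - DAYS_YEAR,
                  .data$end_date >= .data$first_ms_date) |>
    dplyr::distinct(.data$patient_id)
  cls$incident <- ifelse(is.na(cls$first_ms_date), NA,
                         cls$patient_id %in% cov$patient_id)
  cls
}

#' Classify a whole bundle (dialect dispatch + exclusions + incident filter)
#'
#' @param bundle an [ms_bundle()].
#' @return a full classification tibble (see [case-classification]).
#' @export
classify_cases <- function(bundle) {
  cls <- if (bundle$dialect == "CLAIMS_DOD") classify_dod(bundle)
         else classify_cprd(bundle)
  cls <- apply_exclusions(bundle, cls)
  incident_filter(bundle, cls)
}

#' Build the MS cohort
#'
#' Cohort members are classified in a probable or possible tier (never
#' `UNLIKELY` or `NON_CASE`), not excluded, and incident; their cohort entry
#' date is the first MS code date. Per-tier counts over all classified
#' patients are attached as the `tier_counts` attribute.
#'
#' @param bundle an [ms_bundle()].
#' @param classifications optional precomputed [classify_cases()] output.
#' @return tibble of cohort members with an `entry_date` column.
#' @export
build_ms_cohort <- function(bundle, classifications = NULL) {
  cls <- classifications %||% classify_cases(bundle)
  member_tiers <- c("PROBABLE", "POSSIBLE_DEMYELINATING_ONLY",
                    "POSSIBLE_LOW_COUNT", "POSSIBLE_CPRD_SUPPORTED",
                    "POSSIBLE_CPRD_UNSUPPORTED")
  cohort <- cls[cls$tier %in% member_tiers & !cls$excluded &
                  !is.na(cls$incident) & cls$incident, ]
  cohort$entry_date <- cohort$first_ms_date
  attr(cohort, "tier_counts") <- table(cls$tier[cls$tier != "NON_CASE"])
  cohort
}
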