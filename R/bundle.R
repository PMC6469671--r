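#' Construct a record bundle
#'
#' A bundle holds one database dialect's worth of longitudinal coded records:
#' a patients table, enrollment periods, coded clinical events and
#' prescriptions, together with the active codelist. It is the container all
#' downstream stages (classification, matching, ascertainment) consume.
#' Overlapping or abutting enrollment periods are merged on construction so
#' the 1-year prior-enrollment test can look for a single covering period.
#'
#' @param patients tibble with columns
#'   `patient_id,sex,birth_date,geography,dialect`.
#' @param enrollment tibble with `patient_id,start_date,end_date`.
#' @param events tibble with `patient_id,event_date,concept,setting` and an
#'   optional numeric `value` column (used by BMI measurements).
#' @param prescriptions tibble with `patient_id,rx_date,drug_concept,n_issues`.
#' @param codelist a codelist (see [read_codelist()]).
#' @return an object of class `ms_bundle`.
#' @export
ms_bundle <- function(patients, enrollment, events, prescriptions,
                      codelist = default_codelist()) {
  patients <- tibble::as_tibble(patients)
  enrollment <- tibble::as_tibble(enrollment)
  events <- tibble::as_tibble(events)
  prescriptions <- tibble::as_tibble(prescriptions)
  if (!"value" %in% names(events)) events$value <- NA_real_
  if (!"setting" %in% names(events)) events$setting <- "outpatient"
  if (!"n_issues" %in% names(prescriptions)) prescriptions$n_issues <- 1L

  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup) > 0) {
    stop("duplicate patient_id in patients table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (nrow(patients) > 0) {
    bad <- setdiff(unique(patients$dialect), c("CLAIMS_DOD", "EMR_CPRD"))
    if (length(bad) > 0) {
      stop("unknown dialect: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    if (length(unique(patients$dialect)) > 1) {
      stop("a bundle must carry exactly one dialect", call. = FALSE)
    }
  }
  for (tab in list(enrollment, events, prescriptions)) {
    orphan <- setdiff(unique(tab$patient_id), patients$patient_id)
    if (length(orphan) > 0) {
      stop("rows reference unknown patient_id: ",
           paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
    }
  }
  unknown <- setdiff(unique(c(events$concept, prescriptions$drug_concept)),
                     codelist$concept)
  if (length(unknown) > 0) {
    warning("concepts not in codelist (rows kept): ",
            paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }

  structure(
    list(
      patients = patients,
      enrollment = merge_enrollment(enrollment),
      events = events,
      prescriptions = prescriptions,
      codelist = codelist,
      dialect = if (nrow(patients) > 0) patients$dialect[[1]] else NA_character_
    ),
    class = "ms_bundle"
  )
}

#' @export
print.ms_bundle <- function(x, ...) {
  cat(sprintf(
    "<ms_bundle> dialect=%s patients=%d events=%d prescriptions=%d\n",
    x$dialect, nrow(x$patients), nrow(x$events), nrow(x$prescriptions)
  ))
  invisible(x)
}

# Merge overlapping/abutting enrollment periods per patient.
merge_enrollment <- function(enrollment) {
  if (nrow(enrollment) == 0) return(tibble::as_tibble(enrollment))
  if (any(enrollment$start_date > enrollment$end_date)) {
    stop("enrollment period with start_date after end_date", call. = FALSE)
  }
  enrollment <- dplyr::arrange(enrollment, .data$patient_id, .data$start_date)
  dplyr::group_by(enrollment, .data$patient_id) |>
    dplyr::mutate(
      grp = cumsum(as.numeric(.data$start_date) >
                     dplyr::lag(cummax(as.numeric(.data$end_date) + 1),
                                default = -Inf))
    ) |>
    dplyr::group_by(.data$patient_id, .data$grp) |>
    dplyr::summarise(start_date = min(.data$start_date),
                     end_date = max(.data$end_date), .groups = "drop") |>
    dplyr::select("patient_id", "start_date", "end_date")
}

bundle_schemas <- list(
  patients = c("patient_id", "sex", "birth_date", "geography", "dialect"),
  enrollment = c("patient_id", "start_date", "end_date"),
  events = c("patient_id", "event_date", "concept", "setting"),
  prescriptions = c("patient_id", "rx_date", "drug_concept", "n_issues")
)

read_table_checked <- function(path, name, date_cols) {
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(bundle_schemas[[name]], names(tab))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in date_cols) {
    parsed <- as.Date(tab[[col]], format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(tab[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("%s: unparseable date in column %s at data row(s) %s",
                   name, col, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
    tab[[col]] <- parsed
  }
  tab
}

#' Read a record bundle from a directory of CSV files
#'
#' Expects `patients.csv`, `enrollment.csv`, `events.csv` and
#' `prescriptions.csv` (RFC-4180, header row, ISO-8601 dates). Missing
#' required columns, unparseable dates and duplicate patient ids are fatal;
#' concepts absent from the codelist are reported as a warning.
#'
#' @param dir directory containing the four CSV files.
#' @param codelist the codelist to attach.
#' @return an [ms_bundle()].
#' @export
read_bundle <- function(dir, codelist = default_codelist()) {
  pt <- read_table_checked(file.path(dir, "patients.csv"), "patients", "birth_date")
  en <- read_table_checked(file.path(dir, "enrollment.csv"), "enrollment",
                           c("start_date", "end_date"))
  ev <- read_table_checked(file.path(dir, "events.csv"), "events", "event_date")
  rx <- read_table_checked(file.path(dir, "prescriptions.csv"), "prescriptions",
                           "rx_date")
  if ("value" %in% names(ev)) ev$value <- as.numeric(ev$value)
  rx$n_issues <- as.integer(rx$n_issues)
  ms_bundle(pt, en, ev, rx, codelist)
}

#' Write a record bundle to a directory of CSV files
#'
#' Inverse of [read_bundle()]: rows are written in canonical order
#' (patient id, then date) so that write/read round-trips are exact.
#'
#' @param bundle an [ms_bundle()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dplyr::arrange(bundle$patients, .data$patient_id),
                   file.path(dir, "patients.csv"), progress = FALSE)
  readr::write_csv(dplyr::arrange(bundle$enrollment, .data$patient_id,
                                  .data$start_date),
                   file.path(dir, "enrollment.csv"), progress = FALSE)
  readr::write_csv(dplyr::arrange(bundle$events, .data$patient_id,
                                  .data$event_date, .data$concept),
                   file.path(dir, "events.csv"), progress = FALSE)
  readr::write_csv(dplyr::arrange(bundle$prescriptions, .data$patient_id,
                                  .data$rx_date, .data$drug_concept),
                   file.path(dir, "prescriptions.csv"), progress = FALSE)
  invisible(dir)
}

#' Extract a single patient's record
#'
#' @param bundle an [ms_bundle()].
#' @param patient_id one patient identifier.
#' @return an `ms_bundle` restricted to that patient.
#' @export
patient_record <- function(bundle, patient_id) {
  if (!patient_id %in% bundle$patients$patient_id) {
    stop("unknown patient_id: ", patient_id, call. = FALSE)
  }
  structure(
    list(
      patients = bundle$patients[bundle$patients$patient_id == patient_id, ],
      enrollment = bundle$enrollment[bundle$enrollment$patient_id == patient_id, ],
      events = bundle$events[bundle$events$patient_id == patient_id, ],
      prescriptions =
        bundle$prescriptions[bundle$prescriptions$patient_id == patient_id, ],
      codelist = bundle$codelist,
      dialect = bundle$dialect
    ),
    class = "ms_bundle"
  )
}

record_events_in <- function(record, categories, prefix = FALSE) {
  keep <- concepts_in(record$codelist, categories, prefix = prefix)
  record$events[record$events$concept %in% keep, ]
}

#' Count distinct event dates of a category
#'
#' The primitive behind every "diagnoses on different dates" threshold: the
#' number of distinct calendar dates carrying at least one event of the
#' category, optionally restricted to a closed date window. Several codes of
#' the category on one date count once.
#'
#' @param record a single-patient [ms_bundle()] (see [patient_record()]).
#' @param category a concept category name.
#' @param window optional length-2 Date vector (closed interval), or `NULL`
#'   for the whole record.
#' @return non-negative integer count of distinct dates.
#' @export
count_distinct_dates <- function(record, category, window = NULL) {
  ev <- record_events_in(record, category)
  d <- ev$event_date
  if (!is.null(window)) {
    d <- d[d >= window[[1]] & d <= window[[2]]]
  }
  length(unique(d))
}

#' First event date of a category
#'
#' Earliest event date of the category in the record, or `NA` when the
#' category never occurs. The first recorded MS code date defined this way is
#' the cohort entry date.
#'
#' @inheritParams count_distinct_dates
#' @return a Date of length 1 (`NA` when absent).
#' @export
first_date_of <- function(record, category) {
  ev <- record_events_in(record, category)
  if (nrow(ev) == 0) return(as.Date(NA))
  min(ev$event_date)
}
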