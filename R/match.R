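#' Matching key of a case at its index date
#'
#' Controls must match the case exactly on sex, geography unit, completed
#' years of age at the index date, and (by construction, because the case's
#' index date is shared) month and year of cohort entry.
#'
#' @param bundle an [ms_bundle()].
#' @param patient_id patient identifier(s).
#' @param index_date index date(s), recycled against `patient_id`.
#' @return tibble `patient_id, sex, geography, age_years_at_entry,
#'   entry_month`.
#' @export
match_key <- function(bundle, patient_id, index_date) {
  pt <- bundle$patients[match(patient_id, bundle$patients$patient_id), ]
  tibble::tibble(
    patient_id = patient_id,
    sex = pt$sex,
    geography = pt$geography,
    age_years_at_entry = age_at(index_date, pt$birth_date),
    entry_month = format(index_date, "%Y-%m")
  )
}

# control candidate pool: patients MS-free at any time (no MS and no
# demyelinating code ever) — classified/excluded/unlikely MS patients all
# carry MS codes and drop out here automatically
control_pool <- function(bundle) {
  cl <- bundle$codelist
  ms_concepts <- concepts_in(cl, c("ms_diagnosis", "demyelinating_disease"))
  tainted <- unique(bundle$events$patient_id[bundle$events$concept %in% ms_concepts])
  setdiff(bundle$patients$patient_id, tainted)
}

#' Eligible controls for one case
#'
#' Candidates have no MS or demyelinating code at any time in the record,
#' enrollment covering the full closed year before the index date (the same
#' look-back rule imposed on cases), and match the case's key exactly.
#'
#' @param bundle an [ms_bundle()].
#' @param key one-row tibble from [match_key()].
#' @param index_date the case's cohort entry date.
#' @return character vector of candidate patient identifiers.
#' @export
eligible_controls <- function(bundle, key, index_date) {
  pool <- control_pool(bundle)
  pt <- bundle$patients[bundle$patients$patient_id %in% pool, ]
  pt <- pt[pt$sex == key$sex & pt$geography == key$geography, ]
  pt <- pt[age_at(index_date, pt$birth_date) == key$age_years_at_entry, ]
  en <- bundle$enrollment[bundle$enrollment$patient_id %in% pt$patient_id, ]
  covered <- en$patient_id[en$start_date <= index_date - DAYS_YEAR &
                             en$end_date >= index_date]
  unique(covered)
}

#' Assemble the matched non-MS cohort
#'
#' Each incident case receives up to `ratio` controls drawn uniformly
#' without replacement from its eligible candidates; a control serves at
#' most one case across the whole run. Cases are processed in ascending
#' index date, then patient id, so the result is deterministic given the
#' seed. Cases with zero eligible controls are retained in the MS cohort
#' and appear with `set_size = 0`.
#'
#' @param bundle an [ms_bundle()].
#' @param cohort output of [build_ms_cohort()].
#' @param ratio maximum controls per case (default 10).
#' @param seed integer seed for control sampling.
#' @return a tibble of matched pairs (`case_id, control_id, index_date,
#'   set_size`) of class `msphen_matches`; unmatched cases keep one row with
#'   `control_id = NA`.
#' @export
match_cohort <- function(bundle, cohort, ratio = 10, seed = 1L) {
  if (!is.numeric(ratio) || ratio < 1) {
    stop("ratio must be an integer >= 1", call. = FALSE)
  }
  cases <- cohort[order(cohort$entry_date, cohort$patient_id), ]
  pool_ids <- control_pool(bundle)
  pt <- bundle$patients[match(pool_ids, bundle$patients$patient_id), ]
  # index the pool by (sex, geography); age is case-specific
  strata <- split(seq_len(nrow(pt)), paste(pt$sex, pt$geography))
  birth <- pt$birth_date
  # single merged enrollment span is the norm; keep per-patient ranges
  en <- bundle$enrollment[bundle$enrollment$patient_id %in% pool_ids, ]
  en_by_pat <- split(seq_len(nrow(en)), en$patient_id)
  used <- logical(nrow(pt))

  case_keys <- match_key(bundle, cases$patient_id, cases$entry_date)
  out <- vector("list", nrow(cases))
  withr::with_seed(as.integer(seed), {
    for (j in seq_len(nrow(cases))) {
      idx <- cases$entry_date[[j]]
      stratum <- strata[[paste(case_keys$sex[[j]], case_keys$geography[[j]])]]
      cand <- stratum[!used[stratum] &
                        age_at(idx, birth[stratum]) ==
                          case_keys$age_years_at_entry[[j]]]
      if (length(cand) > 0) {
        rows <- unlist(en_by_pat[pt$patient_id[cand]], use.names = FALSE)
        ok <- en$patient_id[rows][en$start_date[rows] <= idx - DAYS_YEAR &
                                    en$end_date[rows] >= idx]
        cand <- cand[pt$patient_id[cand] %in% ok]
      }
      chosen <- resample(cand, min(length(cand), ratio))
      used[chosen] <- TRUE
      out[[j]] <- tibble::tibble(
        case_id = cases$patient_id[[j]],
        control_id = if (length(chosen) > 0) pt$patient_id[chosen] else NA_character_,
        index_date = idx,
        set_size = length(chosen)
      )
    }
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(case_id = character(0), control_id = character(0),
                          index_date = as.Date(character(0)),
                          set_size = integer(0))
  }
  class(res) <- c("msphen_matches", class(res))
  res
}

#' Case + control analysis frame
#'
#' Binds cohort cases (`arm = "ms"`) and their matched controls
#' (`arm = "nonms"`, anchored on the case's index date) into the frame the
#' outcome-ascertainment engine consumes.
#'
#' @param cohort output of [build_ms_cohort()].
#' @param matches output of [match_cohort()].
#' @return tibble `patient_id, arm, index_date, case_id`.
#' @export
analysis_frame <- function(cohort, matches) {
  ctrl <- matches[!is.na(matches$control_id), ]
  dplyr::bind_rows(
    tibble::tibble(patient_id = cohort$patient_id, arm = "ms",
                   index_date = cohort$entry_date,
                   case_id = cohort$patient_id),
    tibble::tibble(patient_id = ctrl$control_id, arm = "nonms",
                   index_date = ctrl$index_date, case_id = ctrl$case_id)
  )
}
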