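#' Generate a synthetic dialect-faithful population
#'
#' Draws a population of coded longitudinal records with known ground-truth
#' MS labels. The claims dialect repeats MS and chronic-condition codes on
#' many distinct dates (MS diagnosis dates follow `1 + NB(mu, size)` with a
#' packaged median of 45) and captures disease-modifying treatments (DMTs)
#' nearly completely; the EMR dialect codes MS once or twice for most cases
#' and captures DMTs only with a small probability. Symptoms, comorbidities,
#' infections and medications are sprinkled at the configured MS / non-MS
#' stratum prevalences inside the windows the ascertainment rules inspect,
#' so every configured prevalence is recoverable by running the rule engine
#' at each patient's reference date. A small configurable fraction of both
#' strata receives injected ALS / stroke / TIA / alternate-diagnosis
#' confounders (non-MS patients additionally receive a single MS code in
#' those scenarios) so that every exclusion branch is exercised.
#'
#' @param config a generator configuration (see [dod_config()]).
#' @param seed integer master seed; the output is deterministic given
#'   `(config, seed)`.
#' @return a list with elements `bundle` (an [ms_bundle()]) and
#'   `ground_truth` (tibble: `patient_id,true_ms,true_onset_date,`
#'   `injected_confounder,ref_date`). Ground truth is never written into the
#'   record tables.
#' @export
generate_population <- function(config, seed = config$seed) {
  validate_config(config)
  withr::with_seed(as.integer(seed), generate_population_impl(config))
}

# k distinct integer offsets in 0..max_off (k capped at max_off + 1)
sample_distinct_offsets <- function(k, max_off) {
  k <- min(k, max_off + 1L)
  sample.int(max_off + 1L, k) - 1L
}

# one event row block: patient indices, dates, one concept
ev_block <- function(pid, dates, concept, setting = "outpatient",
                     value = NA_real_) {
  tibble::tibble(patient_id = pid, event_date = dates, concept = concept,
                 setting = setting, value = value)
}

rx_block <- function(pid, dates, concept) {
  tibble::tibble(patient_id = pid, rx_date = dates, drug_concept = concept,
                 n_issues = 1L)
}

# per-patient distinct-date code blocks: idx/k/lo_off/hi_off aligned vectors;
# dates drawn as anchor - offset with offsets distinct within patient
distinct_date_block <- function(pid, anchor, k, max_off, concept) {
  if (length(pid) == 0) return(NULL)
  offs <- Map(sample_distinct_offsets, k, max_off)
  len <- lengths(offs)
  ev_block(rep(pid, len), rep(anchor, len) - unlist(offs), concept)
}

generate_population_impl <- function(config) {
  n <- config$n_patients
  dialect <- config$dialect
  dod <- dialect == "CLAIMS_DOD"
  pid <- sprintf("P%06d", seq_len(n))

  true_ms <- stats::runif(n) < config$ms_fraction
  p_f <- ifelse(true_ms, config$female_fraction_ms, config$female_fraction_nonms)
  sex <- ifelse(stats::runif(n) < p_f, "F", "M")

  band <- sample.int(length(config$age_band_weights), n, replace = TRUE,
                     prob = config$age_band_weights)
  lo <- vapply(config$age_band_ranges, `[`, integer(1), 1L)[band]
  hi <- vapply(config$age_band_ranges, `[`, integer(1), 2L)[band]
  age <- lo + floor(stats::runif(n) * (hi - lo + 1L))

  bin <- sample.int(length(config$entry_year_weights), n, replace = TRUE,
                    prob = config$entry_year_weights)
  y0 <- vapply(config$entry_year_bins, `[`, integer(1), 1L)[bin]
  y1 <- vapply(config$entry_year_bins, `[`, integer(1), 2L)[bin]
  d0 <- as.numeric(as.Date(paste0(y0, "-01-01")))
  d1 <- as.numeric(as.Date(paste0(y1, "-12-31")))
  entry <- as.Date(d0 + floor(stats::runif(n) * (d1 - d0 + 1)),
                   origin = "1970-01-01")

  # birth such that completed-years age at entry equals `age`
  age_days <- round((age + 0.02 + 0.96 * stats::runif(n)) * 365.25)
  birth <- entry - age_days
  geography <- paste0(config$geography_prefix, "_",
                      sprintf("%02d", sample.int(config$n_geography, n,
                                                 replace = TRUE)))

  pband <- sample.int(length(config$pre_entry_weights), n, replace = TRUE,
                      prob = config$pre_entry_weights)
  plo <- vapply(config$pre_entry_bands, `[`, numeric(1), 1)[pband]
  phi <- vapply(config$pre_entry_bands, `[`, numeric(1), 2)[pband]
  pre_days <- round((plo + stats::runif(n) * (phi - plo)) * 365)
  pre_days <- pmin(pre_days, age_days - 30)   # enrollment starts after birth
  post_days <- round(stats::runif(n, config$post_entry_years[1],
                                  config$post_entry_years[2]) * 365)
  enroll_start <- entry - pre_days
  enroll_end <- entry + post_days

  ev <- list()
  rx <- list()
  strat_p <- function(p_ms, p_nonms) ifelse(true_ms, p_ms, p_nonms)
  pick <- function(p_ms, p_nonms) stats::runif(n) < strat_p(p_ms, p_nonms)
  # uniform date in [entry - back, entry - front], clipped to enrollment
  lookback_date <- function(idx, back, front = 0) {
    b <- pmin(back, pre_days[idx])
    entry[idx] - (front + floor(stats::runif(length(idx)) *
                                  pmax(b - front + 1, 1)))
  }

  ## --- MS disease signal -------------------------------------------------
  demy_only <- true_ms & stats::runif(n) < config$demyelinating_only_frac
  ms_coded <- which(true_ms & !demy_only)
  if (dod) {
    k_ms <- 1L + stats::rnbinom(length(ms_coded),
                                size = config$claims_repeat_model$size,
                                mu = config$claims_repeat_model$mu)
  } else {
    w <- config$emr_ms_code_count_weights
    cls <- sample(names(w), length(ms_coded), replace = TRUE, prob = w)
    k_ms <- ifelse(cls == "1", 1L, ifelse(cls == "2", 2L,
                                          3L + stats::rpois(length(ms_coded), 2)))
  }
  # first MS code at entry; remaining codes on distinct later dates.
  # claims accrual is visit-driven: cap repeat diagnoses at ~1/week of
  # post-entry record, so short records yield low-count (possible) cases
  if (dod) k_ms <- pmin(k_ms, 1L + post_days[ms_coded] %/% 7L)
  ev$ms_first <- ev_block(pid[ms_coded], entry[ms_coded], "ms")
  extra <- pmax(k_ms - 1L, 0L)
  has_extra <- extra > 0 & post_days[ms_coded] > 0
  if (any(has_extra)) {
    i <- ms_coded[has_extra]
    offs <- Map(sample_distinct_offsets, extra[has_extra], post_days[i] - 1L)
    len <- lengths(offs)
    ev$ms_rep <- ev_block(rep(pid[i], len),
                          rep(entry[i], len) + unlist(offs) + 1L, "ms")
  }

  idx_do <- which(demy_only)
  if (length(idx_do) > 0) {
    k <- if (dod) {
      1L + stats::rnbinom(length(idx_do), size = config$claims_repeat_model$size,
                          mu = config$claims_repeat_model$mu)
    } else rep(1L, length(idx_do))
    ev$demy_only <- distinct_date_block(pid[idx_do], enroll_end[idx_do], k,
                                        post_days[idx_do] + pre_days[idx_do],
                                        "demyelinating_disease")
    # anchor the tier: guarantee one demyelinating code at the entry date
    ev$demy_anchor <- ev_block(pid[idx_do], entry[idx_do],
                               "demyelinating_disease")
  }
  extra_demy <- which(true_ms & !demy_only &
                        stats::runif(n) < config$demyelinating_extra_prob)
  if (length(extra_demy) > 0) {
    k <- 1L + stats::rpois(length(extra_demy), 1)
    ev$demy_extra <- distinct_date_block(pid[extra_demy], entry[extra_demy], k,
                                         pre_days[extra_demy],
                                         "demyelinating_disease")
  }

  dmt_concepts <- concepts_in(config_codelist(config), "dmt_or_dalfampridine")
  dmt_cap <- which(true_ms & stats::runif(n) < config$dmt_capture_prob)
  if (length(dmt_cap) > 0) {
    k_rx <- if (dod) {
      # refill-driven: at most ~1 DMT dispensing per 2 weeks of record
      pmin(1L + stats::rnbinom(length(dmt_cap), size = config$dmt_rx_model$size,
                               mu = config$dmt_rx_model$mu),
           1L + post_days[dmt_cap] %/% 14L)
    } else 1L + stats::rpois(length(dmt_cap), 2)
    pidx <- rep(dmt_cap, k_rx)
    dates <- entry[pidx] +
      floor(stats::runif(length(pidx)) * (post_days[pidx] + 1))
    rx$dmt <- rx_block(pid[pidx],
                       dates,
                       sample(dmt_concepts, length(pidx), replace = TRUE))
  }

  ## --- symptoms (any time before entry) ---------------------------------
  for (r in seq_len(nrow(config$symptom_prevalences))) {
    row <- config$symptom_prevalences[r, ]
    i <- which(pick(row$ms, row$nonms))
    if (length(i) > 0) {
      ev[[paste0("sym_", row$concept)]] <-
        ev_block(pid[i], lookback_date(i, pre_days[i]), row$concept)
    }
  }

  ## --- chronic comorbidities (dialect-specific code depth) ---------------
  for (r in seq_len(nrow(config$chronic_prevalences))) {
    row <- config$chronic_prevalences[r, ]
    i <- which(pick(row$ms, row$nonms))
    if (length(i) == 0) next
    k <- if (dod) {
      5L + stats::rnbinom(length(i), size = config$chronic_repeat_model$size,
                          mu = config$chronic_repeat_model$mu)
    } else 1L + stats::rbinom(length(i), 1L, 0.35)
    ev[[paste0("chronic_", row$concept)]] <-
      distinct_date_block(pid[i], entry[i], k, pre_days[i], row$concept)
  }

  ## --- treated pairs: dx + rx within 90 days, > 1 year before entry ------
  for (r in seq_len(nrow(config$treated_pair_prevalences))) {
    row <- config$treated_pair_prevalences[r, ]
    i <- which(pick(row$ms, row$nonms))
    if (length(i) == 0) next
    dx <- lookback_date(i, pre_days[i], front = 456)
    rxd <- dx + round(stats::runif(length(i), -90, 90))
    rxd <- pmax(pmin(rxd, entry[i] - 366), enroll_start[i])
    ev[[paste0("pair_dx_", row$name)]] <- ev_block(pid[i], dx, row$dx_concept)
    rx[[paste0("pair_rx_", row$name)]] <- rx_block(pid[i], rxd, row$rx_concept)
  }

  ## --- cancer -------------------------------------------------------------
  i <- which(pick(config$cancer_prevalence[["ms"]],
                  config$cancer_prevalence[["nonms"]]))
  if (length(i) > 0) {
    hist_route <- stats::runif(length(i)) < 0.5
    ih <- i[hist_route]
    if (length(ih) > 0) {
      ev$cancer_hist <- ev_block(pid[ih], lookback_date(ih, pre_days[ih]),
                                 "cancer_history")
    }
    ic <- i[!hist_route]
    if (length(ic) > 0) {
      if (dod) {
        # >= 5 codes within 183 days: emit 6 distinct dates in a 150-day span
        base <- lookback_date(ic, pre_days[ic], front = 150)
        offs <- Map(sample_distinct_offsets, rep(6L, length(ic)), 150L)
        len <- lengths(offs)
        ev$cancer_clust <- ev_block(rep(pid[ic], len),
                                    rep(base, len) + unlist(offs),
                                    "cancer_primary")
      } else {
        ev$cancer_code <- ev_block(pid[ic], lookback_date(ic, pre_days[ic]),
                                   "cancer_primary")
      }
    }
  }

  ## --- suicidal behaviors -------------------------------------------------
  i <- which(pick(config$suicidal_prevalence[["ms"]],
                  config$suicidal_prevalence[["nonms"]]))
  if (length(i) > 0) {
    cl <- config_codelist(config)
    pool <- intersect(concepts_in(cl, "suicidal_behavior"),
                      active_concepts(cl, dialect))
    ev$suicidal <- ev_block(pid[i], lookback_date(i, pre_days[i]),
                            sample(pool, length(i), replace = TRUE))
  }

  ## --- acute infections in the year before entry --------------------------
  for (r in seq_len(nrow(config$infection_prevalences))) {
    row <- config$infection_prevalences[r, ]
    i <- which(pick(row$ms, row$nonms))
    if (length(i) > 0) {
      ev[[paste0("inf_", row$concept)]] <-
        ev_block(pid[i], lookback_date(i, DAYS_YEAR), row$concept)
    }
  }

  ## --- hospitalized infections --------------------------------------------
  i <- which(pick(config$hospitalized_infection_prevalence[["ms"]],
                  config$hospitalized_infection_prevalence[["nonms"]]))
  if (length(i) > 0) {
    if (dod) {
      ev$hosp_inf <- ev_block(pid[i], lookback_date(i, DAYS_YEAR), "sepsis",
                              setting = "inpatient")
    } else {
      d <- lookback_date(i, DAYS_YEAR - DAYS_WEEK, front = DAYS_WEEK)
      ev$hosp_inf <- ev_block(pid[i], d, "sepsis")
      ev$hosp_marker <- ev_block(
        pid[i], d + sample.int(DAYS_WEEK + 1L, length(i), replace = TRUE) - 1L,
        "hospital_admission")
    }
  }

  ## --- concomitant medications in the year before entry -------------------
  med_block <- function(i, median_k, concept) {
    if (length(i) == 0) return(NULL)
    lam <- ifelse(median_k <= 1, 0.3, median_k - 1)
    k <- 1L + stats::rpois(length(i), lam)
    pidx <- rep(i, k)
    rx_block(pid[pidx],
             entry[pidx] - floor(stats::runif(length(pidx)) * (DAYS_YEAR + 1)),
             concept)
  }
  for (r in seq_len(nrow(config$medication_use))) {
    row <- config$medication_use[r, ]
    i <- which(pick(row$ms, row$nonms))
    med <- ifelse(true_ms[i], row$median_ms, row$median_nonms)
    rx[[paste0("med_", row$class)]] <- med_block(i, med, row$concept)
  }
  ac <- config$anticonvulsants
  has_epi <- pid %in% ev$chronic_epilepsy$patient_id
  p_ac <- ifelse(has_epi, ac$p_epilepsy,
                 strat_p(ac$p_no_epilepsy[["ms"]], ac$p_no_epilepsy[["nonms"]]))
  i <- which(stats::runif(n) < p_ac)
  rx$anticonv <- med_block(i, ifelse(true_ms[i], ac$median[["ms"]],
                                     ac$median[["nonms"]]), ac$concept)

  ## --- smoking and BMI covariates -----------------------------------------
  smoke_lv <- names(config$smoking_dist$ms)
  smoke <- ifelse(true_ms,
                  smoke_lv[sample.int(4L, n, TRUE, prob = config$smoking_dist$ms)],
                  smoke_lv[sample.int(4L, n, TRUE, prob = config$smoking_dist$nonms)])
  i <- which(smoke != "unknown")
  if (length(i) > 0) {
    ev$smoking <- ev_block(pid[i], lookback_date(i, pre_days[i]),
                           paste0("smoking_",
                                  c(current = "current", former = "former",
                                    never = "never")[smoke[i]]))
  }
  bmi_lv <- names(config$bmi_dist$ms)
  bmi_cat <- ifelse(true_ms,
                    bmi_lv[sample.int(5L, n, TRUE, prob = config$bmi_dist$ms)],
                    bmi_lv[sample.int(5L, n, TRUE, prob = config$bmi_dist$nonms)])
  bmi_rng <- list(underweight = c(16, 18.4), normal = c(18.5, 24.9),
                  overweight = c(25, 29.9), obese = c(30, 40))
  i <- which(bmi_cat != "unknown")
  if (length(i) > 0) {
    blo <- vapply(bmi_rng, `[`, numeric(1), 1)[bmi_cat[i]]
    bhi <- vapply(bmi_rng, `[`, numeric(1), 2)[bmi_cat[i]]
    ev$bmi <- ev_block(pid[i], lookback_date(i, pre_days[i]), "bmi_measurement",
                       value = round(stats::runif(length(i), blo, bhi), 1))
  }

  ## --- exclusion-scenario confounder injection ----------------------------
  fr <- config$exclusion_scenario_fracs
  cum <- cumsum(fr)
  u <- stats::runif(n)
  scenario <- rep("none", n)
  scenario[u < cum[["als"]]] <- "als"
  scenario[u >= cum[["als"]] & u < cum[["stroke"]]] <- "stroke"
  scenario[u >= cum[["stroke"]] & u < cum[["tia"]]] <- "tia"
  scenario[u >= cum[["tia"]] & u < cum[["alternate"]]] <- "alternate"

  i <- which(scenario == "als")
  if (length(i) > 0) ev$conf_als <- ev_block(pid[i], lookback_date(i, pre_days[i]), "als")
  i <- which(scenario == "alternate")
  if (length(i) > 0) {
    ev$conf_alt <- ev_block(pid[i], lookback_date(i, pre_days[i]),
                            "other_neuro_alternate")
  }
  i <- which(scenario %in% c("stroke", "tia"))
  if (length(i) > 0) {
    d <- entry[i] + round(stats::runif(length(i), -DAYS_YEAR, DAYS_YEAR))
    d <- pmax(pmin(d, enroll_end[i]), enroll_start[i])
    ev$conf_stroke <- ev_block(pid[i], d,
                               ifelse(scenario[i] == "stroke", "stroke", "tia"))
  }
  # injected non-MS patients receive a single MS code at their reference date
  i <- which(!true_ms & scenario != "none")
  if (length(i) > 0) ev$conf_ms <- ev_block(pid[i], entry[i], "ms")

  ## --- assemble -----------------------------------------------------------
  patients <- tibble::tibble(
    patient_id = pid, sex = sex, birth_date = birth, geography = geography,
    dialect = dialect
  )
  enrollment <- tibble::tibble(patient_id = pid, start_date = enroll_start,
                               end_date = enroll_end)
  events <- dplyr::bind_rows(ev)
  if (nrow(events) == 0) {
    events <- ev_block(character(0), as.Date(character(0)), character(0))
  }
  prescriptions <- dplyr::bind_rows(rx)
  if (is.null(prescriptions) || nrow(prescriptions) == 0) {
    prescriptions <- rx_block(character(0), as.Date(character(0)), character(0))
  }
  bundle <- ms_bundle(patients, enrollment, events, prescriptions,
                      codelist = config_codelist(config))
  ground_truth <- tibble::tibble(
    patient_id = pid,
    true_ms = true_ms,
    true_onset_date = as.Date(ifelse(true_ms, entry, NA), origin = "1970-01-01"),
    injected_confounder = scenario,
    ref_date = entry
  )
  list(bundle = bundle, ground_truth = ground_truth)
}

# codelist used by a config (packaged list unless the config carries one)
config_codelist <- function(config) {
  config$codelist %||% default_codelist()
}

#' Write a generated population to disk
#'
#' Writes the four record CSVs plus `ground_truth.csv` (kept separate from
#' the record files).
#'
#' @param population result of [generate_population()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  write_bundle(population$bundle, dir)
  readr::write_csv(population$ground_truth, file.path(dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(dir)
}
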