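#' Generator configurations
#'
#' A generator configuration fixes every parameter of the synthetic-cohort
#' module: population size and MS fraction, demographic mixes, enrollment
#' depth, the dialect-specific coding process (claims repetition vs sparse
#' EMR coding, disease-modifying-treatment capture), per-concept outcome
#' prevalences in the MS and non-MS strata, medication-use probabilities
#' with target median prescription counts, and the confounder-injection
#' fractions that exercise the exclusion rules.
#'
#' `dod_config()` and `cprd_config()` are the packaged conditions: their
#' demographic and prevalence parameters encode the reference MS/non-MS
#' descriptive-table columns the design emulates (e.g. claims MS female
#' fraction 0.714, treated depression 0.216 vs 0.155), the claims repetition
#' model `1 + NB(mu = 50, size = 3)` has median 45 MS-diagnosis dates, and
#' the EMR MS-code-count weights put 66% of cases at one or two MS codes.
#'
#' @param n_patients population size (default 50,000, a scaled-down study).
#' @param seed default master seed for [generate_population()].
#' @return a list of class `msphen_config`.
#' @name generator-config
NULL

norm_w <- function(x) x / sum(x)

#' @rdname generator-config
#' @export
dod_config <- function(n_patients = 50000, seed = 20190218) {
  cfg <- list(
    dialect = "CLAIMS_DOD",
    n_patients = as.integer(n_patients),
    ms_fraction = 0.02,
    female_fraction_ms = 0.714,
    female_fraction_nonms = 0.50,
    age_band_weights = norm_w(c("<40" = 0.454, "40-59" = 0.426, "60+" = 0.120)),
    age_band_ranges = list("<40" = c(7L, 39L), "40-59" = c(40L, 59L),
                           "60+" = c(60L, 85L)),
    entry_year_bins = list(c(2004L, 2005L), c(2006L, 2010L), c(2011L, 2017L)),
    entry_year_weights = norm_w(c(0.203, 0.415, 0.382)),
    n_geography = 5L,
    geography_prefix = "region",
    pre_entry_bands = list(c(1.25, 2), c(3, 5), c(6, 9), c(10, 14)),
    pre_entry_weights = norm_w(c(0.282, 0.296, 0.263, 0.153)),
    post_entry_years = c(0, 8),
    claims_repeat_model = list(mu = 50, size = 3),
    dmt_rx_model = list(mu = 33, size = 3),
    chronic_repeat_model = list(mu = 3, size = 2),
    dmt_capture_prob = 0.96,
    demyelinating_only_frac = 0.005,
    demyelinating_extra_prob = 0.15,
    emr_ms_code_count_weights = NULL,
    symptom_prevalences = tibble::tribble(
      ~concept,            ~ms,   ~nonms,
      "optic_neuritis",    0.101, 0.001,
      "paresthesia",       0.466, 0.094,
      "paresis",           0.157, 0.030,
      "spasticity_ataxia", 0.226, 0.087,
      "dizziness",         0.256, 0.108,
      "fatigue",           0.306, 0.197,
      "vision_symptoms",   0.201, 0.041,
      "bladder_symptoms",  0.214, 0.156
    ),
    chronic_prevalences = tibble::tribble(
      ~concept,       ~ms,   ~nonms,
      "epilepsy",     0.008, 0.004,
      "asthma_copd",  0.052, 0.045,
      "dyslipidemia", 0.116, 0.116,
      "fracture",     0.043, 0.035
    ),
    treated_pair_prevalences = tibble::tribble(
      ~name,                 ~dx_concept,   ~rx_concept,  ~ms,   ~nonms,
      "treated_depression",  "depression",  "fluoxetine", 0.216, 0.155,
      "treated_hypertension","hypertension","lisinopril", 0.195, 0.181,
      "treated_diabetes",    "diabetes_t2", "metformin",  0.042, 0.045
    ),
    cancer_prevalence = c(ms = 0.034, nonms = 0.035),
    suicidal_prevalence = c(ms = 0.013, nonms = 0.009),
    hospitalized_infection_prevalence = c(ms = 0.020, nonms = 0.012),
    infection_prevalences = tibble::tribble(
      ~concept,                ~ms,   ~nonms,
      "uti",                   0.101, 0.070,
      "respiratory_infection", 0.238, 0.205,
      "skin_infection",        0.050, 0.036,
      "eye_ear_infection",     0.067, 0.053,
      "viral_infection",       0.082, 0.062,
      "meningitis",            0.000, 0.000
    ),
    medication_use = tibble::tribble(
      ~class,            ~concept,     ~ms,   ~nonms, ~median_ms, ~median_nonms,
      "spasticity",      "baclofen",   0.162, 0.056,  1,          1,
      "steroids",        "prednisone", 0.255, 0.128,  1,          1,
      "opioids",         "oxycodone",  0.384, 0.268,  2,          2,
      "antidepressants", "sertraline", 0.284, 0.167,  4,          4,
      "antibiotics",     "amoxicillin",0.466, 0.351,  2,          2,
      "neuropathic_pain","duloxetine", 0.116, 0.029,  2,          2,
      "fatigue",         "amantadine", 0.017, 0.002,  3,          3
    ),
    anticonvulsants = list(
      concept = "gabapentin",
      p_no_epilepsy = c(ms = 0.194, nonms = 0.061),
      p_epilepsy = 0.85,
      median = c(ms = 2, nonms = 2)
    ),
    smoking_dist = list(
      ms = norm_w(c(current = 0.256, former = 0, never = 0.185, unknown = 0.558)),
      nonms = norm_w(c(current = 0.148, former = 0, never = 0.199, unknown = 0.654))
    ),
    bmi_dist = list(
      ms = norm_w(c(underweight = 0.006, normal = 0.099, overweight = 0.109,
                    obese = 0.209, unknown = 0.578)),
      nonms = norm_w(c(underweight = 0.005, normal = 0.097, overweight = 0.107,
                       obese = 0.132, unknown = 0.660))
    ),
    exclusion_scenario_fracs = c(als = 0.001, stroke = 0.003, tia = 0.003,
                                 alternate = 0.002),
    seed = as.integer(seed)
  )
  class(cfg) <- "msphen_config"
  validate_config(cfg)
  cfg
}

#' @rdname generator-config
#' @export
cprd_config <- function(n_patients = 50000, seed = 20190218) {
  cfg <- dod_config(n_patients = n_patients, seed = seed)
  cfg$dialect <- "EMR_CPRD"
  cfg$female_fraction_ms <- 0.702
  cfg$age_band_weights <- norm_w(c("<40" = 0.396, "40-59" = 0.479, "60+" = 0.125))
  cfg$age_band_ranges <- list("<40" = c(2L, 39L), "40-59" = c(40L, 59L),
                              "60+" = c(60L, 89L))
  cfg$entry_year_bins <- list(c(2001L, 2005L), c(2006L, 2010L), c(2011L, 2016L))
  cfg$entry_year_weights <- norm_w(c(0.347, 0.352, 0.301))
  cfg$n_geography <- 10L
  cfg$geography_prefix <- "practice"
  cfg$pre_entry_bands <- list(c(1.25, 2), c(3, 5), c(6, 9), c(10, 20))
  cfg$pre_entry_weights <- norm_w(c(0.124, 0.157, 0.205, 0.514))
  cfg$dmt_capture_prob <- 0.15
  cfg$demyelinating_only_frac <- 0
  cfg$demyelinating_extra_prob <- 0.02
  cfg$emr_ms_code_count_weights <- c("1" = 0.33, "2" = 0.33, "3+" = 0.34)
  cfg$symptom_prevalences <- tibble::tribble(
    ~concept,            ~ms,   ~nonms,
    "optic_neuritis",    0.121, 0.001,
    "paresthesia",       0.398, 0.052,
    "paresis",           0.142, 0.010,
    "spasticity_ataxia", 0.091, 0.020,
    "dizziness",         0.168, 0.078,
    "fatigue",           0.171, 0.131,
    "vision_symptoms",   0.086, 0.010,
    "bladder_symptoms",  0.140, 0.088
  )
  cfg$chronic_prevalences <- tibble::tribble(
    ~concept,       ~ms,   ~nonms,
    "epilepsy",     0.023, 0.016,
    "asthma_copd",  0.160, 0.147,
    "dyslipidemia", 0.056, 0.050,
    "fracture",     0.214, 0.197
  )
  cfg$treated_pair_prevalences$ms <- c(0.213, 0.080, 0.016)
  cfg$treated_pair_prevalences$nonms <- c(0.169, 0.084, 0.017)
  cfg$cancer_prevalence <- c(ms = 0.024, nonms = 0.028)
  cfg$suicidal_prevalence <- c(ms = 0.051, nonms = 0.047)
  cfg$hospitalized_infection_prevalence <- c(ms = 0.019, nonms = 0.008)
  cfg$infection_prevalences <- tibble::tribble(
    ~concept,                ~ms,   ~nonms,
    "uti",                   0.045, 0.029,
    "respiratory_infection", 0.124, 0.112,
    "skin_infection",        0.037, 0.031,
    "eye_ear_infection",     0.049, 0.032,
    "viral_infection",       0.019, 0.015,
    "meningitis",            0.000, 0.000
  )
  cfg$medication_use <- tibble::tribble(
    ~class,            ~concept,     ~ms,   ~nonms, ~median_ms, ~median_nonms,
    "spasticity",      "baclofen",   0.109, 0.033,  2,          1,
    "steroids",        "prednisone", 0.107, 0.035,  1,          1,
    "opioids",         "oxycodone",  0.242, 0.132,  2,          2,
    "antidepressants", "sertraline", 0.268, 0.135,  4,          4,
    "antibiotics",     "amoxicillin",0.350, 0.299,  2,          1,
    "neuropathic_pain","duloxetine", 0.099, 0.016,  3,          3,
    "fatigue",         "amantadine", 0.009, 0.0002, 1,          1
  )
  cfg$anticonvulsants <- list(
    concept = "gabapentin",
    p_no_epilepsy = c(ms = 0.100, nonms = 0.015),
    p_epilepsy = 0.85,
    median = c(ms = 3, nonms = 5)
  )
  cfg$smoking_dist <- list(
    ms = norm_w(c(current = 0.276, former = 0.235, never = 0.411, unknown = 0.078)),
    nonms = norm_w(c(current = 0.224, former = 0.204, never = 0.472, unknown = 0.100))
  )
  cfg$bmi_dist <- list(
    ms = norm_w(c(underweight = 0.025, normal = 0.334, overweight = 0.269,
                  obese = 0.198, unknown = 0.175)),
    nonms = norm_w(c(underweight = 0.021, normal = 0.331, overweight = 0.267,
                     obese = 0.210, unknown = 0.171))
  )
  validate_config(cfg)
  cfg
}

#' @rdname generator-config
#' @export
default_configs <- function(n_patients = 50000, seed = 20190218) {
  list(dod_like = dod_config(n_patients, seed),
       cprd_like = cprd_config(n_patients, seed))
}

#' Validate a generator configuration
#'
#' Checks that all probabilities lie in \[0, 1\] and that every categorical
#' weight vector sums to 1 within 1e-9; problems are reported together with
#' the offending field names.
#'
#' @param config a `msphen_config` list.
#' @return `config`, invisibly, or an error listing invalid fields.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  prob_in <- function(x) all(is.finite(x)) && all(x >= 0) && all(x <= 1)
  probs <- list(
    ms_fraction = config$ms_fraction,
    female_fraction_ms = config$female_fraction_ms,
    female_fraction_nonms = config$female_fraction_nonms,
    dmt_capture_prob = config$dmt_capture_prob,
    demyelinating_only_frac = config$demyelinating_only_frac,
    demyelinating_extra_prob = config$demyelinating_extra_prob,
    cancer_prevalence = config$cancer_prevalence,
    suicidal_prevalence = config$suicidal_prevalence,
    hospitalized_infection_prevalence = config$hospitalized_infection_prevalence,
    exclusion_scenario_fracs = config$exclusion_scenario_fracs,
    symptom_prevalences = unlist(config$symptom_prevalences[c("ms", "nonms")]),
    chronic_prevalences = unlist(config$chronic_prevalences[c("ms", "nonms")]),
    treated_pair_prevalences =
      unlist(config$treated_pair_prevalences[c("ms", "nonms")]),
    infection_prevalences = unlist(config$infection_prevalences[c("ms", "nonms")]),
    medication_use = unlist(config$medication_use[c("ms", "nonms")]),
    anticonvulsants = c(config$anticonvulsants$p_no_epilepsy,
                        config$anticonvulsants$p_epilepsy)
  )
  for (nm in names(probs)) {
    if (!prob_in(probs[[nm]])) bad <- c(bad, nm)
  }
  weights <- list(
    age_band_weights = config$age_band_weights,
    entry_year_weights = config$entry_year_weights,
    pre_entry_weights = config$pre_entry_weights,
    smoking_dist_ms = config$smoking_dist$ms,
    smoking_dist_nonms = config$smoking_dist$nonms,
    bmi_dist_ms = config$bmi_dist$ms,
    bmi_dist_nonms = config$bmi_dist$nonms
  )
  if (!is.null(config$emr_ms_code_count_weights)) {
    weights$emr_ms_code_count_weights <- config$emr_ms_code_count_weights
  }
  for (nm in names(weights)) {
    w <- weights[[nm]]
    if (!prob_in(w) || abs(sum(w) - 1) > 1e-9) bad <- c(bad, nm)
  }
  if (!is.numeric(config$n_patients) || config$n_patients < 1) {
    bad <- c(bad, "n_patients")
  }
  if (length(bad) > 0) {
    stop("invalid generator configuration field(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  invisible(config)
}
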