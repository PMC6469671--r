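#' Run the full study pipeline
#'
#' Orchestrates simulate -> classify -> match -> ascertain -> compare ->
#' validate for one generator configuration, writing every intermediate
#' artifact plus a run manifest (configuration hash, seeds, per-stage row
#' counts). Identical configurations and seeds produce identical artifacts.
#'
#' @param config a generator configuration ([dod_config()] / [cprd_config()]).
#' @param out_dir optional output directory; when given, the record CSVs,
#'   `classifications.csv`, `matched_sets.csv`, `outcomes.csv`, the rendered
#'   tables, `ppv.csv` and `manifest.json` are written there.
#' @param seed master seed; stage seeds are derived from it.
#' @param ratio controls per case.
#' @param outcomes outcome definitions.
#' @param n_per_tier adjudication sample size per tier.
#' @param suppress_below small-cell suppression threshold for rendered
#'   tables.
#' @param quiet suppress per-stage progress messages.
#' @return list with `population`, `classifications`, `cohort`, `matches`,
#'   `frame`, `results`, `comparisons`, `demographics`, `ppv`, `manifest`.
#' @export
run_full_study <- function(config, out_dir = NULL, seed = config$seed,
                           ratio = 10, outcomes = default_outcomes(),
                           n_per_tier = 50, suppress_below = 5,
                           quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- as.integer(seed)
  stage_seeds <- list(simulate = seed, match = seed + 1L, validate = seed + 2L)

  say("simulate: n_patients=%d dialect=%s", config$n_patients, config$dialect)
  population <- generate_population(config, seed = stage_seeds$simulate)
  bundle <- population$bundle

  cls <- classify_cases(bundle)
  cohort <- build_ms_cohort(bundle, cls)
  tiers <- attr(cohort, "tier_counts")
  say("classify: %d classified cases, cohort n=%d (excluded %d, non-incident %d)",
      sum(tiers), nrow(cohort), sum(cls$excluded),
      sum(!cls$incident & !cls$excluded, na.rm = TRUE))

  matches <- match_cohort(bundle, cohort, ratio = ratio,
                          seed = stage_seeds$match)
  frame <- analysis_frame(cohort, matches)
  say("match: %d controls for %d cases (%d fully matched)",
      sum(frame$arm == "nonms"), nrow(cohort),
      sum(matches$set_size == ratio) %/% ratio)

  results <- ascertain_outcomes(bundle, frame, outcomes)
  comparisons <- build_comparisons(results, outcomes)
  demographics <- describe_demographics(bundle, frame, results)
  say("ascertain: %d outcome evaluations", nrow(results))

  samples <- sample_for_adjudication(cls, population$ground_truth,
                                     n_per_tier = n_per_tier,
                                     seed = stage_seeds$validate)
  ppv <- if (nrow(samples) > 0) compute_ppv(samples) else NULL
  if (!is.null(ppv)) {
    say("validate: overall PPV %.3f on %d sampled", ppv$overall$ppv,
        ppv$overall$n_sampled)
  }

  manifest <- list(
    config_hash = rlang::hash(config),
    dialect = config$dialect,
    seeds = stage_seeds,
    counts = list(
      patients = nrow(bundle$patients),
      events = nrow(bundle$events),
      prescriptions = nrow(bundle$prescriptions),
      classified_cases = sum(tiers),
      tier_counts = as.list(tiers),
      excluded = sum(cls$excluded),
      cohort = nrow(cohort),
      controls = sum(frame$arm == "nonms"),
      outcome_rows = nrow(results)
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_population(population, out_dir)
    readr::write_csv(cls, file.path(out_dir, "classifications.csv"),
                     progress = FALSE)
    readr::write_csv(matches, file.path(out_dir, "matched_sets.csv"),
                     progress = FALSE)
    readr::write_csv(results, file.path(out_dir, "outcomes.csv"),
                     progress = FALSE)
    readr::write_csv(demographics, file.path(out_dir, "table2.csv"),
                     progress = FALSE)
    render_tables(comparisons, out_dir, suppress_below = suppress_below)
    ppv_tab <- if (is.null(ppv)) {
      tibble::tibble(tier = character(0), n_sampled = integer(0),
                     n_true = integer(0), ppv = numeric(0),
                     ci_low = numeric(0), ci_high = numeric(0))
    } else {
      tab <- ppv$by_tier
      tab$tier <- as.character(tab$tier)
      tab
    }
    readr::write_csv(ppv_tab, file.path(out_dir, "ppv.csv"), progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(population = population, classifications = cls, cohort = cohort,
       matches = matches, frame = frame, results = results,
       comparisons = comparisons, demographics = demographics, ppv = ppv,
       manifest = manifest)
}
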