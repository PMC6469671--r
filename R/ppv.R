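#' Sample classified cases for adjudication
#'
#' Emulates the questionnaire/chart-review validation step: a stratified
#' uniform sample without replacement from each classification tier
#' (including `UNLIKELY`, which is reported but never a cohort member).
#' Adjudication returns the ground-truth label, optionally flipped with a
#' configurable error probability (default 0, isolating algorithm
#' performance from reviewer noise).
#'
#' @param classifications output of [classify_cases()]; only non-excluded
#'   classified cases (tier other than `NON_CASE`) are sampling strata.
#' @param ground_truth ground-truth tibble from [generate_population()].
#' @param n_per_tier target sample size per tier; strata smaller than this
#'   are sampled completely (with a warning).
#' @param seed integer sampling seed.
#' @param error_rate probability an adjudication flips the true label.
#' @return tibble `patient_id, tier, adjudicated_ms`.
#' @export
sample_for_adjudication <- function(classifications, ground_truth,
                                    n_per_tier = 50, seed = 1L,
                                    error_rate = 0) {
  pool <- classifications[classifications$tier != "NON_CASE" &
                            !classifications$excluded, ]
  withr::with_seed(as.integer(seed), {
    out <- list()
    for (tier in unique(as.character(pool$tier))) {
      ids <- pool$patient_id[pool$tier == tier]
      if (length(ids) < n_per_tier) {
        warning("tier ", tier, " has only ", length(ids),
                " members; sampling the full stratum", call. = FALSE)
      }
      take <- resample(ids, min(length(ids), n_per_tier))
      truth <- ground_truth$true_ms[match(take, ground_truth$patient_id)]
      flip <- stats::runif(length(take)) < error_rate
      out[[tier]] <- tibble::tibble(
        patient_id = take, tier = tier,
        adjudicated_ms = ifelse(flip, !truth, truth)
      )
    }
    dplyr::bind_rows(out)
  })
}

#' Positive predictive value overall and by tier
#'
#' PPV is the adjudicated-true fraction of sampled cases. The overall PPV
#' is computed on the pooled sample and therefore equals the
#' tier-size-weighted average of the tier PPVs exactly. Wilson 95%
#' confidence intervals are attached.
#'
#' @param samples output of [sample_for_adjudication()].
#' @return list with `overall` (one-row tibble) and `by_tier` (one row per
#'   tier), each with `n_sampled, n_true, ppv, ci_low, ci_high`.
#' @export
compute_ppv <- function(samples) {
  if (nrow(samples) == 0) stop("no adjudication samples", call. = FALSE)
  wilson <- function(x, n, z = 1.96) {
    p <- x / n
    den <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / den
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, centre - half), min(1, centre + half))
  }
  summar <- function(x) {
    n <- nrow(x)
    k <- sum(x$adjudicated_ms)
    ci <- wilson(k, n)
    tibble::tibble(n_sampled = n, n_true = k, ppv = k / n,
                   ci_low = ci[1], ci_high = ci[2])
  }
  by_tier <- dplyr::group_by(samples, .data$tier) |>
    dplyr::group_modify(~summar(.x)) |>
    dplyr::ungroup()
  list(overall = summar(samples), by_tier = by_tier)
}
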