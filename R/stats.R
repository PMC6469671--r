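#' Compare two proportions the way the study tables do
#'
#' Builds the 2x2 table (MS present/absent vs non-MS present/absent) and
#' applies the study's test-selection rule: a Pearson chi-square test
#' (1 df, no continuity correction — the SAS PROC FREQ default) unless any
#' observed cell is smaller than 5, in which case a two-sided Fisher's exact
#' test (summing table probabilities no larger than the observed table's) is
#' used. Percentages are rounded half-away-from-zero to one decimal.
#'
#' @param a,b MS-arm counts: with and without the outcome.
#' @param c,d non-MS-arm counts: with and without the outcome.
#' @return one-row tibble `a,b,c,d,pct_ms,pct_nonms,test_used,p_value`.
#' @export
compare_proportions <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (a + b == 0 || c + d == 0) {
    stop("undefined comparison: empty cohort margin", call. = FALSE)
  }
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  statistic <- NA_real_
  if (min(counts) < 5) {
    test_used <- "fisher_exact"
    p <- stats::fisher.test(tab)$p.value
  } else {
    test_used <- "chi_square"
    # suppress the expected-count warning: the selection rule is on observed
    # cells, so all observed cells are >= 5 here by construction
    fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    p <- fit$p.value
    statistic <- unname(fit$statistic)
  }
  tibble::tibble(
    a = a, b = b, c = c, d = d,
    pct_ms = pct1(a, a + b),
    pct_nonms = pct1(c, c + d),
    test_used = test_used,
    statistic = statistic,
    p_value = min(p, 1)
  )
}

#' Per-arm symptom burden
#'
#' Counts, per patient, how many distinct symptom outcomes are present and
#' aggregates the per-arm fractions with at least one and at least two.
#'
#' @param results long results tibble from [ascertain_outcomes()].
#' @param symptom_outcomes names of the symptom outcome rows.
#' @return tibble `arm, n, n_ge1, n_ge2`.
#' @export
symptom_burden <- function(results,
                           symptom_outcomes = default_outcomes()$name[
                             default_outcomes()$table == 3]) {
  x <- results[results$outcome %in% symptom_outcomes, ]
  per <- dplyr::summarise(dplyr::group_by(x, .data$arm, .data$patient_id),
                          k = sum(.data$present), .groups = "drop")
  dplyr::summarise(dplyr::group_by(per, .data$arm),
                   n = dplyr::n(),
                   n_ge1 = sum(.data$k >= 1),
                   n_ge2 = sum(.data$k >= 2),
                   .groups = "drop")
}

#' Median prescription count among users
#'
#' Median of `n_rx` restricted to patients with at least one prescription;
#' even-sized sets take the lower median so every reported median is an
#' attainable integer count. `NA` when there are no users.
#'
#' @param n_rx integer vector of per-patient prescription counts.
#' @return integer median among users, or `NA`.
#' @export
median_rx_among_users <- function(n_rx) {
  users <- n_rx[n_rx >= 1]
  if (length(users) == 0) return(NA_integer_)
  sorted <- sort(users)
  as.integer(sorted[ceiling(length(sorted) / 2)])
}

#' Build the MS vs non-MS comparison table
#'
#' One row per binary outcome with the 2x2 counts, percentages, test choice
#' and p-value (see [compare_proportions()]); medication outcomes also carry
#' the median prescription count among users in each arm. The two
#' symptom-burden rows (at least one / at least two symptoms) are appended.
#'
#' @param results long results from [ascertain_outcomes()].
#' @param outcomes the outcome definitions used.
#' @return tibble with one row per outcome.
#' @export
build_comparisons <- function(results, outcomes = default_outcomes()) {
  binary <- outcomes[outcomes$kind != "CATEGORICAL_COVARIATE", ]
  n_ms <- length(unique(results$patient_id[results$arm == "ms"]))
  n_nonms <- length(unique(results$patient_id[results$arm == "nonms"]))
  # an arm can be empty in tiny smoke runs; report counts without tests then
  safe_compare <- function(a, b, c, d) {
    if (a + b == 0 || c + d == 0) {
      return(tibble::tibble(a = a, b = b, c = c, d = d,
                            pct_ms = if (a + b > 0) pct1(a, a + b) else NA_real_,
                            pct_nonms = if (c + d > 0) pct1(c, c + d) else NA_real_,
                            test_used = NA_character_, p_value = NA_real_))
    }
    compare_proportions(a, b, c, d)
  }
  rows <- vector("list", nrow(binary) + 2)
  for (r in seq_len(nrow(binary))) {
    o <- binary[r, ]
    x <- results[results$outcome == o$name, ]
    a <- sum(x$present & x$arm == "ms")
    cc <- sum(x$present & x$arm == "nonms")
    cmp <- safe_compare(a, n_ms - a, cc, n_nonms - cc)
    cmp$outcome <- o$name
    cmp$table <- o$table
    cmp$label <- o$label
    if (o$kind == "MEDICATION_USE") {
      cmp$median_rx_ms <- median_rx_among_users(x$n_rx[x$arm == "ms"])
      cmp$median_rx_nonms <- median_rx_among_users(x$n_rx[x$arm == "nonms"])
    } else {
      cmp$median_rx_ms <- NA_integer_
      cmp$median_rx_nonms <- NA_integer_
    }
    rows[[r]] <- cmp
  }
  burden <- symptom_burden(results)
  mk_burden <- function(col, outcome, label) {
    pull1 <- function(arm) {
      v <- burden[burden$arm == arm, ][[col]]
      if (length(v) == 0) 0L else v
    }
    g1 <- pull1("ms")
    g2 <- pull1("nonms")
    cmp <- safe_compare(g1, n_ms - g1, g2, n_nonms - g2)
    cmp$outcome <- outcome
    cmp$table <- 3L
    cmp$label <- label
    cmp$median_rx_ms <- NA_integer_
    cmp$median_rx_nonms <- NA_integer_
    cmp
  }
  rows[[nrow(binary) + 1]] <-
    mk_burden("n_ge1", "symptoms_ge1", "At least one of the symptoms above")
  rows[[nrow(binary) + 2]] <-
    mk_burden("n_ge2", "symptoms_ge2", "At least two of the symptoms above")
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "outcome", "table", "label")
}

fmt_count <- function(n) formatC(n, big.mark = ",", format = "d")

fmt_cell <- function(n, pct, suppress_below) {
  ifelse(n > 0 & n < suppress_below, "NR",
         paste0(fmt_count(n), " (", formatC(pct, format = "f", digits = 1), ")"))
}

#' Render the comparison tables to delimited files
#'
#' Writes `table3.csv` ... `table6.csv` (cells formatted `N (pct)` with
#' thousands separators, small cells suppressed as `NR`, significance
#' markers at each table's footnote threshold) plus a machine-readable
#' `comparisons.csv`.
#'
#' @param comparisons output of [build_comparisons()].
#' @param out_dir output directory.
#' @param suppress_below suppress non-zero cells smaller than this count.
#' @return invisible character vector of files written.
#' @export
render_tables <- function(comparisons, out_dir, suppress_below = 5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thresholds <- c("2" = 1e-4, "3" = 1e-3, "4" = 1e-2, "5" = 1e-2, "6" = 1e-2)
  files <- character(0)
  for (tb in sort(unique(comparisons$table))) {
    x <- comparisons[comparisons$table == tb, ]
    thr <- thresholds[[as.character(tb)]]
    out <- tibble::tibble(
      outcome = x$label,
      ms = fmt_cell(x$a, x$pct_ms, suppress_below),
      nonms = fmt_cell(x$c, x$pct_nonms, suppress_below),
      significant = ifelse(x$p_value < thr, "*", "")
    )
    if (tb == 6) {
      out$median_ms <- x$median_rx_ms
      out$median_nonms <- x$median_rx_nonms
    }
    f <- file.path(out_dir, paste0("table", tb, ".csv"))
    readr::write_csv(out, f, progress = FALSE)
    files <- c(files, f)
  }
  machine <- comparisons[, c("outcome", "a", "b", "c", "d", "pct_ms",
                             "pct_nonms", "test_used", "p_value")]
  f <- file.path(out_dir, "comparisons.csv")
  readr::write_csv(machine, f, progress = FALSE)
  invisible(c(files, f))
}

#' Describe cohort demographics (matched-characteristics table)
#'
#' Tabulates sex, age bands, entry period and the smoking/BMI covariates per
#' arm at the index date.
#'
#' @param bundle an [ms_bundle()].
#' @param frame analysis frame from [analysis_frame()].
#' @param results optional precomputed [ascertain_outcomes()] results (for
#'   the covariate rows).
#' @return tibble `block, level, n_ms, pct_ms, n_nonms, pct_nonms`.
#' @export
describe_demographics <- function(bundle, frame, results = NULL) {
  pt <- bundle$patients[match(frame$patient_id, bundle$patients$patient_id), ]
  age <- age_at(frame$index_date, pt$birth_date)
  blocks <- list(
    sex = pt$sex,
    age_band = cut(age, c(-Inf, 39, 59, Inf),
                   labels = c("<40", "40-59", "60+")),
    entry_year = as.integer(format(frame$index_date, "%Y"))
  )
  if (!is.null(results)) {
    for (cov in c("smoking", "bmi_band")) {
      x <- results[results$outcome == cov, ]
      blocks[[cov]] <- x$category_value[match(frame$patient_id, x$patient_id)]
    }
  }
  n_ms <- sum(frame$arm == "ms")
  n_nonms <- sum(frame$arm == "nonms")
  rows <- list()
  for (bl in names(blocks)) {
    v <- as.character(blocks[[bl]])
    for (lv in sort(unique(v))) {
      a <- sum(v == lv & frame$arm == "ms")
      cc <- sum(v == lv & frame$arm == "nonms")
      rows[[paste(bl, lv)]] <- tibble::tibble(
        block = bl, level = lv,
        n_ms = a, pct_ms = pct1(a, n_ms),
        n_nonms = cc, pct_nonms = pct1(cc, n_nonms)
      )
    }
  }
  dplyr::bind_rows(rows)
}
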