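# independent brute-force oracles, written directly from the published rule
# wording, deliberately in a different style from the package internals

# claims-dialect tier as a plain decision table over evidence counts
oracle_dod_tier <- function(ms_dates, demy_dates, dmt_rx) {
  msdemy <- ms_dates + demy_dates  # test grids use disjoint dates
  if (msdemy < 1 || dmt_rx < 1) return("NON_CASE")
  if (msdemy >= 10 && dmt_rx >= 5) return("PROBABLE")
  if (ms_dates >= 5 && dmt_rx >= 10) return("PROBABLE")
  if (demy_dates >= 1 && ms_dates == 0) return("POSSIBLE_DEMYELINATING_ONLY")
  if (ms_dates >= 1 && ms_dates <= 10 && dmt_rx >= 1 && dmt_rx <= 10) {
    return("POSSIBLE_LOW_COUNT")
  }
  "NON_CASE"
}

oracle_cprd_tier <- function(ms_dates, support) {
  if (ms_dates == 0) return("NON_CASE")
  if (ms_dates >= 2 && support) return("PROBABLE")
  if (support) return("POSSIBLE_CPRD_SUPPORTED")
  if (ms_dates >= 2) return("POSSIBLE_CPRD_UNSUPPORTED")
  "UNLIKELY"
}

# textbook Pearson statistic: sum over cells of (O - E)^2 / E
oracle_chisq <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  x2 <- sum((o - e)^2 / e)
  list(statistic = x2, p_value = stats::pchisq(x2, df = 1, lower.tail = FALSE))
}

# two-sided Fisher p by full hypergeometric enumeration over the margin
oracle_fisher <- function(a, b, c, d) {
  m <- a + b          # MS margin
  n <- c + d          # non-MS margin
  k <- a + c          # total with outcome
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# naive per-record scans over raw event tables -----------------------------

oracle_concept_dates <- function(bundle, id, concepts) {
  ev <- bundle$events
  sort(unique(ev$event_date[ev$patient_id == id & ev$concept %in% concepts]))
}

oracle_chronic <- function(bundle, id, concepts, index, threshold) {
  d <- oracle_concept_dates(bundle, id, concepts)
  length(unique(d[d <= index])) >= threshold
}

oracle_acute <- function(bundle, id, concepts, index, window) {
  d <- oracle_concept_dates(bundle, id, concepts)
  any(d <= index & (is.infinite(window) | d >= index - window))
}

oracle_pair <- function(bundle, id, dx_concepts, rx_concepts, index) {
  dx <- oracle_concept_dates(bundle, id, dx_concepts)
  dx <- dx[dx <= index]
  rx <- bundle$prescriptions
  rxd <- rx$rx_date[rx$patient_id == id & rx$drug_concept %in% rx_concepts]
  rxd <- rxd[rxd <= index]
  for (x in dx) for (y in rxd) if (abs(as.numeric(x - y)) <= 90) return(TRUE)
  FALSE
}

oracle_cancer_dod <- function(bundle, id, index) {
  hist <- oracle_concept_dates(bundle, id, "cancer_history")
  if (any(hist <= index)) return(TRUE)
  d <- oracle_concept_dates(bundle, id, "cancer_primary")
  d <- d[d <= index]
  if (length(d) >= 10) return(TRUE)
  if (length(d) >= 5) {
    for (i in seq_along(d)) {
      if (sum(d >= d[i] & d <= d[i] + 183) >= 5) return(TRUE)
    }
  }
  FALSE
}
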