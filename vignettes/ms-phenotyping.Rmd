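---
title: "Phenotyping MS in claims and EMR data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping MS in claims and EMR data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msphen)
```

## The problem

Multiple sclerosis has no single diagnostic code event that can be trusted
on its own. In a reimbursement-driven claims system, a presumptive MS code
is entered every time a visit or test investigates the disease, so a single
code is weak evidence but chronic true cases accumulate dozens of codes and
disease-modifying-treatment (DMT) dispensings. In a general-practice EMR,
the opposite holds: a confirmed diagnosis is entered once and rarely
repeated, and DMTs administered in specialty clinics never reach the
record. A credible case definition must therefore be *database-specific*,
and its certainty tiers must be validated (by chart review or
questionnaire) before the cohort is used for comparative questions.

`msphen` implements this design end to end on dialect-tagged record
bundles: a claims dialect (`CLAIMS_DOD`) and an EMR dialect (`EMR_CPRD`),
each with its own classifier, chronic-outcome thresholds, cancer rule and
hospitalized-infection rule. Because the source databases are proprietary,
the package ships a seeded synthetic-cohort generator with ground-truth
labels; every downstream stage is exercised and tested against it.

## Case algorithms and their assumptions

Both classifiers operate on two per-patient summaries: distinct calendar
dates carrying MS (or demyelinating-disease) codes, and DMT prescription
rows (sum of issues). Counting *dates* rather than rows makes the claims
algorithm robust to same-day duplicate billing; counting prescription
*rows* preserves the dispensing intensity that the claims tiers rely on.
One convention is applied everywhere — including the exclusion rules,
where the source wording ("less than five MS codes") does not say whether
rows or dates are meant; using dates throughout keeps every threshold
consistent and testable.

Tier precedence is explicit: a record satisfying both the probable and a
possible definition is probable. The EMR "support" notion (symptom or
symptomatic-treatment codes accompanying an MS diagnosis) counts evidence
on either side of the first MS code, since the algorithm text sets no
window for it; support categories cover MS symptoms, symptomatic
treatments, and the spasticity / neuropathic-pain / fatigue drug classes.

The demyelinating-only claims tier has, by definition, no MS code; its
cohort entry date is anchored on the first demyelinating code instead —
the only coherent choice, and the only tier where it matters.

Exclusions run in a fixed order (ALS at any time; alternate diagnosis with
few MS codes; stroke/TIA up to 183 days after the first MS code with few
MS codes), so an excluded patient carries one deterministic reason.
Incident cases require a single merged enrollment period covering the full
closed year before the first MS code; enrollment periods are merged at
load so that abutting registration segments do not spuriously fail this
test.

## Matching

Matching is exact on sex, geography unit and completed-years age at the
index date; month/year of entry is shared by construction because a
control inherits its case's index date. Controls must be MS-free at *any*
time in the record (no MS and no demyelinating code, before or after the
index) so that later-diagnosed cases cannot contaminate the comparison
arm, and must satisfy the same 1-year prior-enrollment rule as cases so
that look-back windows are comparable. Controls are sampled uniformly
without replacement and serve at most one case; cases are processed in
ascending index-date order, which makes the whole stage a deterministic
function of the seed. Cases with no eligible control remain in the MS
cohort, flagged with an empty set — cohort membership is decided before
matching.

## Outcome rules

All look-back windows are closed intervals with fixed lengths (1 year =
365 days, 6 months = 183 days, 1 week = 7 days, 90 days literal); events
strictly after the index date never influence any outcome. The claims
cancer rule's "five or more codes within 6 months of each other" is read
as: some set of five codes spans at most 183 days, implemented as a
sliding window over the sorted distinct dates. The claims meningitis rule
("multiple codes plus supporting treatment or symptom codes") is
parameterized as ≥ 2 distinct-date codes plus ≥ 1
symptom/symptomatic-treatment/antibiotic record in the same 1-year window.
Symptom outcomes are ascertained as ≥ 1 code ever on/before the index in
*both* dialects: the ≥ 5-code depth requirement is stated for chronic
comorbidities only, and transient symptoms cannot be expected to
re-bill the way chronic conditions do.

Overdose is an active suicidal-behavior concept only in the EMR codelist
(the claims grouping does not include it); the rule engine respects
per-dialect concept activation generally.

## The synthetic generator: what it emulates

The packaged configurations (`dod_config()`, `cprd_config()`) fix the
study conditions: 50,000 patients, 2% true-MS fraction, female fractions
0.714 (claims) / 0.702 (EMR) among MS and 0.50 otherwise, age-band and
entry-year mixes, and per-outcome prevalences for the MS and non-MS strata
fixed row by row by the reference descriptive tables the design emulates.
The claims coding
process draws MS diagnosis dates as `1 + NB(mu = 50, size = 3)` (median
45) and DMT rows as `1 + NB(mu = 33, size = 3)` (median 30), both capped
by visit/refill rates (one coded visit per week, one dispensing per two
weeks of post-entry record) so that short records produce the low-count
possible tier rather than impossibly dense coding. The EMR process draws
MS code counts from weights putting 66% of cases at one or two codes, and
captures DMTs with probability 0.15 versus 0.96 in claims. A small
fraction of both strata receives injected ALS/stroke/TIA/alternate
confounders — non-MS patients additionally receive one MS code in those
scenarios — so every exclusion branch and the false-positive path into the
unlikely tier are exercised.

Window-limited events are placed inside the window their rule inspects
(infections and medications in the year before the reference date, chronic
and symptom codes anywhere in the pre-entry record), which makes every
configured prevalence exactly recoverable by running the rule engine at
each patient's own reference date. Treated-pair episodes
(diagnosis + prescription within 90 days) are deliberately placed more
than 455 days before entry so that treated chronic status and recent
medication use are independent, separately recoverable parameters; the
minimum pre-entry record is correspondingly 1.25 years. This is a
simplification — in real data a treated hypertensive usually also fills
prescriptions in the final year — and it means the generator understates
medication use among the treated-chronic subgroup.

Other deliberate non-realisms: no disease progression or post-entry
outcome dynamics; symptom codes appear once rather than re-billing;
control patients' window-limited events are anchored on their own
reference date, so a control matched to a case with a distant index date
contributes an attenuated window prevalence in full-pipeline tables (the
parameter-recovery tests therefore evaluate at reference dates, and the
matched-table tests assert structure, not window prevalences). Passing
tests consequently demonstrate correctness of the *rules and plumbing*
under known conditions, not fidelity of any particular real-world
prevalence.

The generator is fully vectorized over a single seeded stream
(`withr::with_seed`), making output a deterministic function of
`(config, seed)`; per-patient hashed substreams were considered and
rejected as needless complexity once generation is vectorized — no
insertion order exists to be independent of.

## Numerical and formatting choices

- Dates are ISO-8601 in files and `Date` (integer days) internally.
- Percentages round half away from zero to one decimal (matching
  published-table arithmetic; base R's banker's rounding would print
  12.25% as 12.2).
- Chi-square is Pearson, 1 df, *without* continuity correction — the
  default of the SAS release the original analyses used; Fisher's exact
  p sums table probabilities ≤ the observed table's (two-sided). The test
  switch keys on *observed* cells < 5, a literal reading of "cell sizes".
- Medians among users take the lower median for even counts, so every
  reported median is an attainable integer prescription count.
- Age is completed years at the index date via `floor(days / 365.25)`;
  cases and controls are aged by the same function, so matching is
  consistent even when the approximation differs from calendar age by a
  day.
- BMI bands are half-open (`[18.5, 25)`, `[25, 30)`, `30+`); non-positive
  BMI values are data errors. Missing covariates categorize as `unknown`.
- Degenerate inputs: an empty cohort margin is an error in
  `compare_proportions()` but tolerated (NA statistics) in whole-table
  builds so tiny smoke runs complete; a case with zero eligible controls
  is retained unmatched; empty adjudication pools skip PPV.

## Problem sizes in the shipped tests

Unit tests run on hand-built records and populations of 60–8,000
patients. The property and calibration tests use the packaged 50,000-
patient populations once per dialect (cached within a test run), a
2,197-point exhaustive grid for the claims classifier against a
brute-force rule table, 120 random records against naive-scan oracles,
and 20 seeded 6,000-patient populations for the PPV ordering check. The
acceptance script regenerates the 50,000-patient claims population from
scratch at the supplied seed.

## Known limitations

- Codelists are illustrative concept groupings, not real ICD/Read/NDC
  vocabularies; all logic runs on abstract concepts by design.
- The possible-tier share of the claims cohort emerges from the
  record-length distribution and is smaller than shares reported for real
  claims cohorts; the conjunctive tier definition (1–10 diagnoses *and*
  1–10 prescriptions) also leaves some mid-count records unclassified — a
  disjunctive reading ("fewer than five of either") would catch them.
  Sub-counts are surfaced in the classification output so either
  convention can be tabulated.
- PPV validation adjudicates against generator ground truth (optionally
  with a configurable error rate); it cannot model questionnaire
  non-response or reviewer disagreement.
- Smoking and BMI are point-in-time latest-value covariates; no
  longitudinal exposure modeling is attempted.
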