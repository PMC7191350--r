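---
title: "Linkage, indicator and comparison methods in cohortlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage, indicator and comparison methods in cohortlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortlink)
```

`cohortlink` measures participation bias: how people enrolled in a
clinical HIV cohort differ from the surveillance population they are
drawn from. This vignette documents the methods, their assumptions, the
tunable parameters, and the design decisions taken where more than one
reasonable choice existed.

## Deterministic match-key cascade

A roster record is compared against the registry with eleven composite
keys, tried in a fixed priority order; the record links at the first
(lowest) level at which its key is defined and equals a registry
record's key. The keys, in `match_key_specs()` order:

| Level | Components | Review |
|---|---|---|
| 1 | SSN | no |
| 2 | first (1–6), last, DOB | no |
| 3 | last (1), last (3–8), first (2–8), DOB | no |
| 4 | last (1), last (3–8), first (2–8), birth month, birth year | no |
| 5 | last (1), last (3–8), first (2–8), birth day, birth year | no |
| 6 | last, first (1–2), DOB | no |
| 7 | last (1–3), first (1–3), DOB | yes |
| 8 | last (1–4), first (1–4), birth year | yes |
| 9 | first (1–3), last (1–3), birth month, birth year | yes |
| 10 | first (1–3), last (1–3), birth day, birth year | yes |
| 11 | first (1–3), last (1–3), birth month, birth year | yes |

Conventions, chosen once and asserted by tests:

* **Letter slices are 1-based and inclusive.** "Letters 3 through 8"
  means positions 3..8 of the normalized name. A name shorter than the
  slice's *start* yields no key at that level (the record simply cannot
  participate there); a name shorter than the slice's *end* contributes
  the characters it has. This keeps keys well-defined for short names
  without inventing padding.
* **Normalization** upper-cases, trims, folds diacritics to ASCII and
  strips non-alphabetic characters from names; an SSN is treated as
  missing unless exactly nine digits survive. Normalization is
  idempotent.
* **Level 3 skips letter 2 of the last name** as published — the skip
  plausibly tolerates a single typo — and is implemented exactly as
  printed.
* **Level 11 is textually identical to level 9**, which makes it
  unreachable (any pair agreeing at 11 already agreed at 9). It is
  implemented as printed rather than "repaired", and `cascade_match()`
  notes this once per run. Whether the duplication is a typo (perhaps
  birth day + birth year was intended) cannot be resolved from the
  published algorithm.
* **Direction**: the roster is matched into the registry, not
  bidirectionally.

The cascade is checked against an exhaustive all-pairs, all-levels
oracle on instances of several hundred records per side, and its output
is independent of input row order (ordering is internal).

## Validation score and review policy

Deterministic key equality says nothing about how much of the full
identifier set agrees, so every candidate link also receives a
field-agreement score on a 0–100 scale: a weighted sum of per-field
agreement (SSN exact; names by normalized Levenshtein similarity; birth
day, month, year exact), rescaled over the *comparable* fields so that
full agreement is 100 and none is 0. Default weights are SSN 40, first
name 15, last name 15, and 10 per DOB component — SSN agreement alone is
never sufficient, full name + DOB agreement is. A field enters the
denominator only when it can be compared: an SSN or DOB missing on
either side is no information (the Fellegi–Sunter convention), while a
name blank on exactly one side counts as disagreement. Links scoring
below the acceptance threshold — default 80, the conventional cutoff for
this kind of agreement score — are eliminated as `below_threshold`.

Matches through keys 7–11 rest on partial names only and, in practice,
go to clerical review; a library cannot automate judgment, so review is
modeled as a policy: `auto_reject` eliminates all review-flagged links
(`manual_review`), while `score_gate` (default) and `auto_accept` retain
them subject to the score threshold. Because the threshold gates *every*
level — accepted links must always score at or above it — `score_gate`
and `auto_accept` coincide under the defaults; they are kept as distinct
policies to make the analyst's intent explicit and to leave room for a
threshold applied only to review levels.

Deduplication enforces one-to-one linkage (a cohort participant is one
surveillance person). Among competing candidate links the survivor has
the lowest key level, then the highest score, then the lowest registry
id (then roster id) — a total order, so results are deterministic.

## Population definitions

A person counts as living with HIV in the jurisdiction at the end of
the lab window if they (1) have an HIV diagnosis, (2) their *most
recent* lab on or before the window end (2016-12-31) falls inside the
window (2011-01-01 onward) and carries the jurisdiction-residence flag,
and (3) they are alive at the end of the outcome year. The definition
keys on the last lab: a person whose most recent lab precedes the window
is excluded even if older labs fell within it. Cohort members are
analysis-eligible when their consent date lies in the enrollment window
(closed interval on both ends), they are jurisdiction residents, and
they have not withdrawn; withdrawn or otherwise ineligible enrollees are
analyzed in the non-cohort group. All date intervals in the package are
closed. Eligibility emits a per-criterion exclusion tally (first failing
criterion) that conserves the input count, and the cohort/non-cohort
partition of the eligible set is checked to be disjoint and exhaustive.

Vital status is taken from the supplied end-of-outcome-year flag rather
than re-derived from death dates, which surveillance systems adjudicate
upstream.

## Continuum indicators

* **Stage** (CDC): stage 3 if CD4 count < 200 cells/µL, CD4% < 14, or
  an AIDS-defining opportunistic infection; stage 1 if count > 500 (or,
  with no count, percentage ≥ 29); stage 2 for counts 200–500 inclusive
  (or percentages 14–28). When count and percentage disagree the count
  wins, following the CDC convention; the published boundary leaves
  28–29% ambiguous and is closed here as stage 1 iff percentage ≥ 29.
  Stage in the outcome year uses the most recent count and percentage on
  or before 2017-12-31; no CD4 on record gives `"unknown"`.
* **Receipt of care**: at least one CD4 or VL lab in the calendar year.
* **Suppression**: VL ≤ 200 copies/mL, threshold inclusive.
  "Detectable" is its complement (VL > 200); the source definitions
  never state it. Suppression *in* the outcome year has two common
  readings — any suppressed VL that year, or suppression at the
  chronologically last VL of the year — which differ exactly for people
  who rebound late in the year. Both are computed
  (`suppressed_any_2017`, `suppressed_last_lab_2017`); the reporting
  layer tabulates the last-lab form, and a person with no outcome-year
  VL has last-lab status undefined (tabulated and modeled as not
  suppressed).
* **Time to suppression**: days from the first VL > 200 to the first
  subsequent VL ≤ 200, divided by 30.4375 (the mean Gregorian month);
  the 24-month category boundary is inclusive in "0–24". Undefined when
  no detectable VL precedes the first suppressed one (e.g. a person
  whose first-ever reported VL is already suppressed).
* **Comorbidity flags**: at least one STI / confirmed chronic HBV /
  confirmed chronic HCV event dated 2011–2016. Only RNA-confirmed
  chronic hepatitis events belong in the input; antibody-only records
  are an upstream exclusion.

The stage rules are verified against an exhaustive truth-table oracle
over a grid of (count, percentage, OI) values, and the suppression and
time-to-suppression rules against a literal re-implementation on random
VL sequences.

## Comparison statistics

Categorical characteristics are cross-tabulated with column percentages
rounded half-up to one decimal (surveillance display convention — base
R's half-to-even would disagree with published cells), and tested with
Pearson chi-square (no continuity correction). Continuous measures use
one-way equal-variance ANOVA. Degenerate tables produce output without a
test rather than an error.

Adjusted group contrasts are prevalence ratios from log-link binomial
regression — the appropriate effect measure when outcomes are common,
where odds ratios exaggerate — adjusting for gender identity, age at the
end of the outcome year, race/ethnicity, time since HIV diagnosis, and
transmission mode. Age and time since diagnosis enter as continuous
covariates (no categorization is published). The log-binomial likelihood
is maximized by IRLS from a feasible start (intercept at the log overall
prevalence, slopes at zero, convergence tolerance 1e-12); since its
parameter space is constrained (fitted probabilities must stay below 1),
non-convergence is routine at high prevalence, and the standard remedy
is applied automatically: a log-link Poisson fit with HC0 sandwich
standard errors, flagged as `poisson_robust_fallback` in every output
that carries it. Wald 95% intervals throughout; an exposure level with
zero outcome events returns a non-converged result rather than a
runaway estimate. Missing covariates are handled complete-case with a
logged count. A with-no-covariates fit reproduces the closed-form ratio
of proportions and its delta-method CI to 1e-8, and calibration is
checked by simulation: at n = 20,000 over 500 replicates the log-APR
bias is below 0.02 and the Wald CI covers both a true ratio of 1.25 and
a null ratio of 1.0 at the nominal rate.

The four standard models are: retention in any care; ever virally
suppressed; suppressed at the last outcome-year lab; and, among the
ever-suppressed with a defined time to suppression, suppression after
more than 24 months. The published analysis reports the first two
adjusted contrasts on different scales in different places (odds ratios
in its abstract, prevalence ratios in its results table); the
prevalence-ratio specification matches the stated model and is the
primary output here.

## The synthetic-data generator

The generator exists so that linkage and the downstream statistics can
be validated against known truth. It emulates a registry of `n_persons`
(default 13,000, sized to the population the reporting layer
replicates): identifiers from a bundled static name list (no network),
unique nine-digit SSNs, demographics from configurable categorical
distributions with the surveillance schema's labels, diagnosis dates
with mean time since diagnosis ≈ 11.5 years, ~3% deceased, ~5%
non-resident, and 2011–2016 history labs with Poisson counts
(`labs_per_person_mean`, default 6) at uniform dates, each lab a VL, CD4
count or CD4 percentage.

Enrollment is a latent per-person Bernoulli flag (probability
`enroll_fraction`, default 0.4) drawn at registry generation, because
clinical behavior is group-differential: the `outcome_model`
probabilities are a conditional chain chosen so each is directly
identifiable from the output —

* `care_in_year` = P(≥ 1 lab in the outcome year); a care-year lab
  count of 1 + Poisson(1) is added when it fires;
* `ever_suppressed` = P(any VL ≤ 200 in 2011–2017); an ever-suppressed
  person receives a suppression-onset date in the lab window, VLs
  detectable before it and suppressed after it, with the
  definition-carrying labs (a detectable VL before onset, a suppressed
  VL after) guaranteed to exist;
* `suppressed_last_lab` = P(last outcome-year VL suppressed | in care,
  ever suppressed, and ≥ 1 outcome-year VL), drawn for the final
  outcome-year VL — allowing late rebound, which is what separates the
  two in-year suppression definitions.

Defaults follow the replicated clinical table's margins: cohort (0.835,
0.837, 0.88), non-cohort (0.717, 0.781, 0.90). Because lab kinds are
sampled (not every care encounter includes a VL), the *marginal*
last-lab suppression prevalence is lower than its conditional parameter;
the recovery tests condition exactly as defined. Identifier corruption
(per-record probabilities: missing SSN 0.15, name typo 0.05, name
truncation 0.05, DOB component error 0.02 — conventions, since no
identifier-quality statistics are published for real registries) is
applied in a fixed order (missing → typo → truncation → DOB), so one
seed fully determines the output; names shorter than three characters
pass through untouched. The roster draws its RNG stream from
`seed + 1`, making registry and roster independently reproducible, and
an identical configuration reproduces byte-identical CSVs.

What the generator does *not* emulate — and hence what green tests do
not establish about real data: realistic name/SSN frequency structure
(family clusters, culturally correlated spellings, shared typos),
address and migration history (residence is a single boolean),
reporting lag, duplicate registry enrollments, ART regimens or
adherence, or demographic differences between enrollees and
non-enrollees (only *clinical* behavior is group-differential, so the
synthetic demographic tables are null contrasts). Linkage recall under
the default corruption rates is a property of those conventions, not an
estimate of any real registry's match rate.

## Numerical and operational choices

* Percentages: half-up rounding with a 1e-9 representation guard.
* Score ties in deduplication resolve by id order; all outputs are
  sorted internally, so runs are independent of input row order.
* Degenerate inputs: empty rosters, empty truth sets, single-category
  tables and zero-event exposures all return defined results (NA plus a
  warning, or a non-converged flag) instead of errors; genuinely
  invalid configuration stops with the offending field named.
* Problem sizes: the bundled tests exercise the cascade oracle at ≤ 500
  records per side, generator laws at n = 10,000, estimator calibration
  at 500 replicates of n = 20,000, and the end-to-end pipeline at
  n ≈ 600–2,000; the acceptance script runs the pipeline at n = 13,000.
  These sizes make every law-of-large-numbers band (3 standard errors)
  tight enough to detect real defects while keeping a full run in
  minutes.
* CSV artifacts are ISO-8601/UTF-8 with mandatory headers and
  round-trip losslessly; the run manifest records seeds and per-stage
  record counts, and contains no timestamps, so identical configurations
  produce bit-identical run directories.

## Known limitations

Manual review is necessarily a policy abstraction; the score is a
transparent surrogate for proprietary linkage-software scores and its
weights, while conventional, are not calibrated to any real error model
(no EM-estimated m/u probabilities, no phonetic encodings). The
eligibility layer trusts the supplied vital-status and residence flags.
The published tables this package's reporting layer mirrors contain
several internally inconsistent cells (percentages that do not match
their printed counts and denominators, one impossible CI ordering);
where a convention had to be chosen the consistent reading was
implemented and the inconsistent cells are simply not used as
references.
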