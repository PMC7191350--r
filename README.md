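# cohortlink

Deterministic surveillance-to-cohort record linkage and HIV
care-continuum comparison.

## The problem

HIV surveillance registries record every diagnosed person in a
jurisdiction; clinical cohort studies enroll the subset who consent at
participating care sites. Whether cohort findings generalize depends on
how the enrolled differ from the source population — participation
(selection) bias. Measuring that requires (1) linking the cohort roster
to the registry at the person level using imperfect identifiers, (2)
deriving each person's clinical indicators from longitudinal surveillance
labs, and (3) contrasting the linked (cohort) and unlinked (non-cohort)
groups with appropriate statistics. `cohortlink` implements that pipeline
end to end, plus a synthetic registry/roster generator with known
ground-truth links so linkage accuracy and the downstream statistics can
be validated against truth.

## Methods at the core

**Match-key cascade.** Records are compared with 11 deterministic keys,
tried in priority order; a pair links at the lowest level whose keys are
defined on both sides and equal. Level 1 is the SSN; level 2 is first
name (letters 1–6) + last name + date of birth; levels 3–11 use
progressively coarser name slices and DOB components (e.g. level 7 =
last 1–3 + first 1–3 + DOB). Letter indexing is 1-based inclusive; a
name shorter than a slice's start yields no key at that level. Matches
through the partial-name keys 7–11 are flagged for review and handled by
an explicit policy. Deduplication enforces one-to-one linkage with the
tie-break (lowest level, highest score, lowest registry id).

**Validation score.** Each candidate link gets a 0–100 field-agreement
score

  S = 100 · Σᵢ wᵢ aᵢ / Σᵢ wᵢ,

with default weights w = (SSN 40, first name 15, last name 15, birth
day/month/year 10 each); aᵢ is exact agreement for SSN and DOB
components and a normalized edit-distance similarity for names, and the
sums run over the fields comparable on both sides. Links scoring below
the acceptance threshold (default 80) are eliminated.

**Continuum indicators.** CDC disease stage from the last reported CD4
count/percentage (stage 3 if count < 200, percentage < 14 or an
opportunistic infection; count takes precedence); receipt of care = ≥ 1
CD4/VL lab in the calendar year; viral suppression = VL ≤ 200 copies/mL
(ever in 2011–2017, at the last 2017 lab, or any 2017 lab); time from
first detectable VL to first subsequent suppressed VL, categorized at 24
months; STI/HBV/HCV diagnosis flags over 2011–2016.

**Comparison layer.** Contingency tables with half-up one-decimal column
percentages and Pearson chi-square tests, one-way ANOVA for continuous
measures, and adjusted prevalence ratios (APR) from log-link binomial
regression — `log P(Y=1|X) = β₀ + β₁·cohort + γ'Z` with Z = gender
identity, age, race/ethnicity, time since diagnosis, transmission mode —
with a robust-variance (HC0) log-Poisson fallback when the log-binomial
IRLS fit does not converge.

## Worked example

A full synthetic run — simulate a 2,000-person registry and its cohort
roster, link, define the eligible population, derive indicators, and
compare:

```r
library(cohortlink)
res <- run_pipeline(list(out_dir = file.path(tempdir(), "demo"), seed = 42,
                         sim = list(n_persons = 2000)))
res$manifest$flow[c("n_registry", "n_roster", "n_eligible", "n_accepted",
                    "n_cohort", "n_noncohort")]
#> 2000, 784, 1827, 781, 711, 1116
sprintf("precision %.3f recall %.3f",
        res$linkage_eval$precision, res$linkage_eval$recall)
#> "precision 1.000 recall 0.996"
res$linkage_eval$by_level
#>   1   2   3   4   5   6   7   8   9  10  11
#> 672  97   1   0   1   4   6   0   0   0   0
head(res$tables$table2, 3)
#>   characteristic    category     cohort  noncohort p_value
#>  Gender identity        Male 516 (72.6) 782 (70.1)    .345
#>  Gender identity      Female 180 (25.3) 315 (28.2)
#>  Gender identity Transgender   15 (2.1)   19 (1.7)
res$tables$table4
#>                            model         apr_95ci                  method    n
#>          model1_retained_in_care 1.12 (1.07-1.18)            log_binomial 1827
#>           model2_ever_suppressed 1.06 (1.01-1.11)            log_binomial 1827
#>  model3_suppressed_last_lab_2017 1.23 (1.09-1.39)            log_binomial 1827
#>              model4_tts_over_24m 1.02 (0.94-1.10) poisson_robust_fallback 1447
```

Reading the output: of 2,000 simulated registry persons, 784 enrolled in
the roster; 1,827 met the population definition (alive, diagnosed, last
2011–2016 lab with a local address). The cascade accepted 781 links —
all correct (precision 1.000) and missing only 0.4% of true links —
mostly at key 1 (SSN) with the rest caught by the fallback keys after
identifier corruption. The cohort group then shows the configured excess
in care engagement and suppression (APRs above 1), as a real evaluation
would.

Every stage is also callable on its own (`link_records()`,
`select_plwh()`, `derive_indicators()`, `run_model_suite()`), and a thin
command-line front end lives at `inst/cli/cohortlink.R`. The methods
vignette (`vignettes/cohort-linkage-methods.Rmd`) documents the rules,
parameters and design choices in detail.

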