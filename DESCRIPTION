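Package: cohortlink
Title: Deterministic Record Linkage and Care-Continuum Comparison for
    HIV Surveillance and Cohort Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links a person-level HIV surveillance registry to a clinical
    cohort enrollment roster with an 11-level deterministic match-key
    cascade (SSN, then progressively coarser name/date-of-birth keys),
    one-to-one deduplication, review-policy handling of the partial-name
    keys, and a field-agreement validation score on a 0-100 scale.
    Derives per-person HIV care-continuum indicators (CDC disease stage,
    receipt of care, viral suppression, time to suppression, STI/HBV/HCV
    comorbidity flags), applies surveillance-population and cohort
    eligibility rules, and compares cohort with non-cohort groups via
    contingency tables with Pearson chi-square tests, one-way ANOVA, and
    adjusted prevalence ratios from log-binomial regression with a
    robust-variance Poisson fallback. Includes a synthetic registry and
    roster generator with configurable identifier corruption and known
    ground-truth links for evaluating linkage precision and recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
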