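#' Demographic comparison table (counts, column percentages, tests)
#'
#' One row per category of gender identity, race/ethnicity and
#' transmission risk with "n (pct)" per group and a Pearson chi-square
#' p-value per characteristic; plus median (IQR) age, mean (SD) years
#' since diagnosis (one-way ANOVA p-values), and the in-window STI / HBV
#' / HCV comorbidity rows (chi-square on the 2 x 2 flag table).
#'
#' @param persons eligible persons with demographics.
#' @param indicators per-person indicator table.
#' @param group named factor from [partition_groups()].
#' @param window a [study_window()].
#' @return data frame with columns `characteristic`, `category`,
#'   `cohort`, `noncohort`, `p_value`.
#' @export
demographic_table <- function(persons, indicators, group,
                              window = study_window()) {
  g <- group[persons$person_id]
  ref <- as.Date(sprintf("%d-12-31", window$outcome_year))
  ind <- indicators[match(persons$person_id, indicators$person_id), , drop = FALSE]
  denom <- table(g)

  rows <- list()
  cat_row <- function(characteristic, values, categories) {
    tab <- build_table(values, g, characteristic, categories)
    out <- data.frame(
      characteristic = characteristic,
      category = rownames(tab$counts),
      cohort = mapply(format_count_pct, tab$counts[, "cohort"], tab$totals["cohort"]),
      noncohort = mapply(format_count_pct, tab$counts[, "noncohort"], tab$totals["noncohort"]),
      p_value = c(format_pvalue(tab$p_value), rep("", nrow(tab$counts) - 1L)),
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  }
  flag_row <- function(characteristic, flag) {
    tab <- build_table(ifelse(flag, "yes", "no"), g, characteristic,
                       categories = c("yes", "no"))
    data.frame(characteristic = characteristic, category = "yes",
               cohort = format_count_pct(tab$counts["yes", "cohort"], denom["cohort"]),
               noncohort = format_count_pct(tab$counts["yes", "noncohort"], denom["noncohort"]),
               p_value = format_pvalue(tab$p_value), stringsAsFactors = FALSE)
  }

  rows$gender <- cat_row("Gender identity", persons$gender_identity,
                         c("Male", "Female", "Transgender"))
  rows$race <- cat_row("Race/ethnicity", persons$race_ethnicity,
                       c("White", "Black", "Hispanic", "Other"))
  rows$risk <- cat_row("Transmission risk", persons$transmission_risk,
                       c("MSM", "IDU", "MSM/IDU", "Heterosexual contact",
                         "Perinatal", "Other", "Not identified"))

  age <- years_between(persons$dob, ref)
  age_p <- anova_continuous(age, g)$p_value
  rows$age <- data.frame(
    characteristic = "Age in years, median (IQR)", category = "",
    cohort = sprintf("%.0f (%.0f)", stats::median(age[g == "cohort"]),
                     stats::IQR(age[g == "cohort"])),
    noncohort = sprintf("%.0f (%.0f)", stats::median(age[g == "noncohort"]),
                        stats::IQR(age[g == "noncohort"])),
    p_value = format_pvalue(age_p), stringsAsFactors = FALSE)

  ysd <- years_between(persons$hiv_diagnosis_date, ref)
  ysd_p <- anova_continuous(ysd, g)$p_value
  rows$ysd <- data.frame(
    characteristic = "Time since HIV diagnosis in years, mean (SD)", category = "",
    cohort = sprintf("%.1f (%.1f)", mean(ysd[g == "cohort"]),
                     stats::sd(ysd[g == "cohort"])),
    noncohort = sprintf("%.1f (%.1f)", mean(ysd[g == "noncohort"]),
                        stats::sd(ysd[g == "noncohort"])),
    p_value = format_pvalue(ysd_p), stringsAsFactors = FALSE)

  rows$sti <- flag_row("STI diagnosis between 2011-2016", ind$sti_2011_2016)
  rows$hbv <- flag_row("Hepatitis B coinfection between 2011-2016", ind$hbv_2011_2016)
  rows$hcv <- flag_row("Hepatitis C coinfection between 2011-2016", ind$hcv_2011_2016)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clinical-outcome comparison table
#'
#' Ever stage 3, engagement in care in the outcome year, median (IQR)
#' outcome-year CD4, most-recent CD4 category (denominator: persons with
#' a CD4 on record), ever virally suppressed, suppressed at the last
#' outcome-year lab (persons with no outcome-year VL count as not
#' suppressed), and the time-to-suppression category (denominator:
#' persons with a defined category).
#'
#' @inheritParams demographic_table
#' @return data frame like [demographic_table()].
#' @export
clinical_table <- function(indicators, group, window = study_window()) {
  g <- group[indicators$person_id]
  denom <- table(g)
  rows <- list()

  flag_row <- function(characteristic, flag) {
    tab <- build_table(ifelse(flag, "yes", "no"), g, characteristic,
                       categories = c("yes", "no"))
    data.frame(characteristic = characteristic, category = "yes",
               cohort = format_count_pct(tab$counts["yes", "cohort"], denom["cohort"]),
               noncohort = format_count_pct(tab$counts["yes", "noncohort"], denom["noncohort"]),
               p_value = format_pvalue(tab$p_value), stringsAsFactors = FALSE)
  }

  rows$stage3 <- flag_row("Ever stage 3 diagnosis", indicators$ever_stage3)
  rows$care <- flag_row(sprintf("Engaged in HIV care in %d", window$outcome_year),
                        indicators$care_2017)

  cd4 <- indicators$cd4_2017
  has <- !is.na(cd4) & !is.na(g)
  cd4_p <- tryCatch(anova_continuous(cd4[has], g[has])$p_value,
                    error = function(e) NA_real_)
  rows$cd4 <- data.frame(
    characteristic = sprintf("CD4 count in %d, median (IQR)", window$outcome_year),
    category = "",
    cohort = sprintf("%.0f (%.0f)", stats::median(cd4[has & g == "cohort"]),
                     stats::IQR(cd4[has & g == "cohort"])),
    noncohort = sprintf("%.0f (%.0f)", stats::median(cd4[has & g == "noncohort"]),
                        stats::IQR(cd4[has & g == "noncohort"])),
    p_value = format_pvalue(cd4_p), stringsAsFactors = FALSE)

  cat_tab <- build_table(indicators$cd4_recent_cat, g, "CD4 count, most recent",
                         categories = c("<200", "200-500", ">500"))
  rows$cd4cat <- data.frame(
    characteristic = "CD4 count, most recent",
    category = rownames(cat_tab$counts),
    cohort = mapply(format_count_pct, cat_tab$counts[, "cohort"], cat_tab$totals["cohort"]),
    noncohort = mapply(format_count_pct, cat_tab$counts[, "noncohort"], cat_tab$totals["noncohort"]),
    p_value = c(format_pvalue(cat_tab$p_value), "", ""), stringsAsFactors = FALSE)

  rows$ever <- flag_row("Virally suppressed between 2011-2017",
                        indicators$ever_suppressed)
  rows$last <- flag_row(sprintf("Virally suppressed at last lab in %d", window$outcome_year),
                        !is.na(indicators$suppressed_last_lab_2017) &
                          indicators$suppressed_last_lab_2017)

  tts_tab <- build_table(indicators$tts_category, g, "Time to first known viral suppression",
                         categories = c("0-24", ">24"))
  rows$tts <- data.frame(
    characteristic = "Time to first known viral suppression (months)",
    category = rownames(tts_tab$counts),
    cohort = mapply(format_count_pct, tts_tab$counts[, "cohort"], tts_tab$totals["cohort"]),
    noncohort = mapply(format_count_pct, tts_tab$counts[, "noncohort"], tts_tab$totals["noncohort"]),
    p_value = c(format_pvalue(tts_tab$p_value), ""), stringsAsFactors = FALSE)

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format the adjusted-model results table
#'
#' @param models data frame from [run_model_suite()].
#' @return data frame with `model` and `apr_95ci` ("APR (low-high)",
#'   two decimals) plus the method flag.
#' @export
model_table <- function(models) {
  data.frame(
    model = models$model,
    apr_95ci = ifelse(models$converged,
                      sprintf("%.2f (%.2f-%.2f)", models$apr, models$ci_low,
                              models$ci_high),
                      "not converged"),
    method = models$method,
    n = models$n,
    stringsAsFactors = FALSE
  )
}

#' Render the three comparison tables from pipeline artifacts
#'
#' @param artifacts list as returned by [run_pipeline()] (needs
#'   `eligible`, `indicators`, `group`, `models`, `window`).
#' @return list with `table2`, `table3`, `table4` formatted data frames.
#' @export
render_tables <- function(artifacts) {
  list(
    table2 = demographic_table(artifacts$eligible, artifacts$indicators,
                               artifacts$group, artifacts$window),
    table3 = clinical_table(artifacts$indicators, artifacts$group,
                            artifacts$window),
    table4 = model_table(artifacts$models)
  )
}
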