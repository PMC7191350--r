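#' Simulation configuration for the synthetic registry and roster
#'
#' Collects and validates all parameters of the synthetic-data generator:
#' population size, enrollment fraction, identifier-corruption rates,
#' group-differential clinical-outcome probabilities, lab intensity, the
#' enrollment/lab window and the seed. An identical configuration
#' (including seed) reproduces byte-identical outputs.
#'
#' The `outcome_model` probabilities form a conditional chain so that each
#' is directly identifiable from the generated data: `care_in_year` is the
#' probability of having at least one lab in the outcome year;
#' `ever_suppressed` the probability of any viral load at or below
#' 200 copies/mL during the suppression window; `suppressed_last_lab` the
#' probability that the chronologically last outcome-year viral load is
#' suppressed, conditional on being in care that year, being an
#' ever-suppressed person, and having an outcome-year viral load.
#'
#' @param n_persons number of registry persons (>= 1).
#' @param enroll_fraction probability a registry person enrolls in the
#'   cohort roster.
#' @param corruption_rates named list of per-record probabilities:
#'   `ssn_missing`, `name_typo`, `name_truncation`, `dob_component_error`.
#' @param outcome_model named list with elements `cohort` and `noncohort`,
#'   each a named list of probabilities `care_in_year`, `ever_suppressed`,
#'   `suppressed_last_lab`.
#' @param labs_per_person_mean Poisson mean of the number of 2011-2016
#'   history labs per person.
#' @param study_window length-2 character/Date vector, enrollment and lab
#'   window `[start, end]`.
#' @param seed integer RNG seed.
#' @param demographics named list of categorical probability tables for
#'   `gender_identity`, `race_ethnicity`, `transmission_risk`.
#' @param comorbidity_model per-group in-window diagnosis probabilities
#'   (`sti`, `hbv`, `hcv`), plus `oi` (AIDS-defining opportunistic
#'   infection, group-independent).
#' @param deceased_fraction probability of `vital_status_end_2017 =
#'   "deceased"`.
#' @param nonresident_fraction probability a person's labs carry a
#'   non-jurisdiction address flag.
#' @param withdrawal_fraction probability an enrolled roster member later
#'   withdrew (withdrawn members are analyzed as non-cohort).
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_persons = 13000,
                       enroll_fraction = 0.4,
                       corruption_rates = list(ssn_missing = 0.15,
                                               name_typo = 0.05,
                                               name_truncation = 0.05,
                                               dob_component_error = 0.02),
                       outcome_model = list(
                         cohort = list(care_in_year = 0.835,
                                       ever_suppressed = 0.837,
                                       suppressed_last_lab = 0.88),
                         noncohort = list(care_in_year = 0.717,
                                          ever_suppressed = 0.781,
                                          suppressed_last_lab = 0.90)),
                       labs_per_person_mean = 6,
                       study_window = c("2011-01-01", "2016-12-31"),
                       seed = 1L,
                       demographics = default_demographics(),
                       comorbidity_model = list(
                         cohort = list(sti = 0.174, hbv = 0.017, hcv = 0.054),
                         noncohort = list(sti = 0.189, hbv = 0.013, hcv = 0.044),
                         oi = 0.05),
                       deceased_fraction = 0.03,
                       nonresident_fraction = 0.05,
                       withdrawal_fraction = 0.01) {
  if (!(is.numeric(n_persons) && length(n_persons) == 1L && !is.na(n_persons) &&
        n_persons >= 1)) {
    config_error("n_persons", "must be a positive integer")
  }
  if (!is_prob(enroll_fraction)) config_error("enroll_fraction", "must be in [0,1]")
  for (f in c("ssn_missing", "name_typo", "name_truncation", "dob_component_error")) {
    if (!is_prob(corruption_rates[[f]])) {
      config_error(paste0("corruption_rates$", f), "must be in [0,1]")
    }
  }
  for (g in c("cohort", "noncohort")) {
    for (f in c("care_in_year", "ever_suppressed", "suppressed_last_lab")) {
      if (!is_prob(outcome_model[[g]][[f]])) {
        config_error(paste0("outcome_model$", g, "$", f), "must be in [0,1]")
      }
    }
    for (f in c("sti", "hbv", "hcv")) {
      if (!is_prob(comorbidity_model[[g]][[f]])) {
        config_error(paste0("comorbidity_model$", g, "$", f), "must be in [0,1]")
      }
    }
  }
  if (!is_prob(comorbidity_model$oi)) config_error("comorbidity_model$oi", "must be in [0,1]")
  if (!(is.numeric(labs_per_person_mean) && labs_per_person_mean > 0)) {
    config_error("labs_per_person_mean", "must be a positive real")
  }
  window <- as.Date(study_window)
  if (length(window) != 2L || any(is.na(window)) || !(window[1] < window[2])) {
    config_error("study_window", "must be two dates with start < end")
  }
  if (!(is.numeric(seed) && length(seed) == 1L && !is.na(seed))) {
    config_error("seed", "must be a single integer")
  }
  for (v in names(demographics)) {
    p <- demographics[[v]]
    if (!is.numeric(p) || is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      config_error(paste0("demographics$", v), "must be named probabilities summing to 1")
    }
  }
  for (f in c("deceased_fraction", "nonresident_fraction", "withdrawal_fraction")) {
    if (!is_prob(get(f))) config_error(f, "must be in [0,1]")
  }
  structure(list(
    n_persons = as.integer(n_persons),
    enroll_fraction = enroll_fraction,
    corruption_rates = corruption_rates,
    outcome_model = outcome_model,
    labs_per_person_mean = labs_per_person_mean,
    study_window = window,
    seed = as.integer(seed),
    demographics = demographics,
    comorbidity_model = comorbidity_model,
    deceased_fraction = deceased_fraction,
    nonresident_fraction = nonresident_fraction,
    withdrawal_fraction = withdrawal_fraction
  ), class = "sim_config")
}

#' Default demographic category distributions
#'
#' Category labels follow the surveillance reporting schema (gender
#' identity: Male/Female/Transgender; race/ethnicity:
#' White/Black/Hispanic/Other; transmission risk: MSM/IDU/MSM-IDU/
#' Heterosexual contact/Perinatal/Other/Not identified), with marginal
#' probabilities matching the combined DC population the package's
#' reporting layer replicates.
#'
#' @return named list of named probability vectors.
#' @export
default_demographics <- function() {
  list(
    gender_identity = c(Male = 0.721, Female = 0.262, Transgender = 0.017),
    race_ethnicity = c(White = 0.160, Black = 0.746, Hispanic = 0.068,
                       Other = 0.026),
    transmission_risk = c(MSM = 0.443, IDU = 0.106, `MSM/IDU` = 0.032,
                          `Heterosexual contact` = 0.277, Perinatal = 0.011,
                          Other = 0.001, `Not identified` = 0.130)
  )
}
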