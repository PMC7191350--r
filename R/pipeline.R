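# CSV writers/readers for the pipeline artifacts. Dates are written as
# ISO-8601, files are UTF-8 with a mandatory header row; a blank cell is a
# missing value (a missing SSN reads back as the empty string, its
# in-memory form).

#' Write a pipeline table as CSV
#'
#' @param df data frame; Date columns are serialized as ISO-8601.
#' @param path output file path.
#' @export
write_table_csv <- function(df, path) {
  for (cl in names(df)) {
    if (inherits(df[[cl]], "Date")) df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
}

#' Read a pipeline table from CSV
#'
#' @param path file path.
#' @param date_cols,num_cols,lgl_cols,chr_blank_cols column names to
#'   convert to Date / numeric / logical, and character columns whose
#'   missing values read back as `""` (the SSN convention).
#' @return data frame.
#' @export
read_table_csv <- function(path, date_cols = character(0),
                           num_cols = character(0), lgl_cols = character(0),
                           chr_blank_cols = character(0)) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = "", fileEncoding = "UTF-8")
  for (cl in intersect(date_cols, names(df))) df[[cl]] <- as.Date(df[[cl]])
  for (cl in intersect(num_cols, names(df))) df[[cl]] <- as.numeric(df[[cl]])
  for (cl in intersect(lgl_cols, names(df))) df[[cl]] <- as.logical(df[[cl]])
  for (cl in intersect(chr_blank_cols, names(df))) {
    df[[cl]][is.na(df[[cl]])] <- ""
  }
  df
}

#' @rdname read_table_csv
#' @export
read_persons_csv <- function(path) {
  read_table_csv(path, date_cols = c("dob", "hiv_diagnosis_date"),
                 lgl_cols = c("jurisdiction_resident", "enrollee"),
                 chr_blank_cols = "ssn")
}

#' @rdname read_table_csv
#' @export
read_roster_csv <- function(path) {
  read_table_csv(path, date_cols = c("dob", "consent_date", "withdrawal_date"),
                 lgl_cols = "jurisdiction_resident", chr_blank_cols = "ssn")
}

#' @rdname read_table_csv
#' @export
read_labs_csv <- function(path) {
  read_table_csv(path, date_cols = "lab_date", num_cols = "value",
                 lgl_cols = "jurisdiction_resident")
}

#' @rdname read_table_csv
#' @export
read_diagnoses_csv <- function(path) {
  read_table_csv(path, date_cols = "event_date")
}

#' Run the full surveillance-to-cohort comparison pipeline
#'
#' Orchestrates simulate (or load) -> link -> define population ->
#' indicators -> compare from one configuration, writing every artifact
#' and a manifest to `out_dir`. A failure in any stage aborts with the
#' stage name; artifacts already written are preserved. Outputs are
#' bit-stable: the same configuration (including seed) reproduces
#' identical files.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `out_dir`; either `sim` (arguments for [sim_config()]) for a
#'   synthetic run or `inputs` (paths `registry`, `labs`, `diagnoses`,
#'   `roster`); optional `seed` (overrides the sim seed); optional
#'   `linkage` (`threshold`, `policy`, `levels`); optional `window`
#'   (arguments for [study_window()]).
#' @return (invisibly) a list with all in-memory artifacts: `persons`,
#'   `labs`, `diagnoses`, `roster`, `truth`, `decisions`, `eligible`,
#'   `exclusions`, `cohort_roster`, `group`, `indicators`, `models`,
#'   `tables`, `linkage_eval`, `manifest`, `window`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) config_error("out_dir", "must be provided")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  window <- do.call(study_window, as.list(config$window))
  lnk <- config$linkage
  threshold <- if (is.null(lnk$threshold)) 80 else lnk$threshold
  policy <- if (is.null(lnk$policy)) "score_gate" else lnk$policy
  levels <- if (is.null(lnk$levels)) 1:11 else lnk$levels

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(config$sim)) {
    sim_args <- as.list(config$sim)
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    scfg <- stage("simulate", do.call(sim_config, sim_args))
    reg <- stage("simulate", generate_registry(scfg))
    ros <- stage("simulate", generate_roster(reg$persons, scfg))
    persons <- reg$persons
    labs <- reg$labs
    diagnoses <- reg$diagnoses
    roster <- ros$roster
    truth <- ros$truth
    stage("simulate", {
      write_table_csv(persons[setdiff(names(persons), "enrollee")],
                      file.path(out_dir, "registry.csv"))
      write_table_csv(labs, file.path(out_dir, "labs.csv"))
      write_table_csv(diagnoses, file.path(out_dir, "diagnoses.csv"))
      write_table_csv(roster, file.path(out_dir, "roster.csv"))
      write_table_csv(truth, file.path(out_dir, "truth.csv"))
    })
  } else if (!is.null(config$inputs)) {
    persons <- stage("load", read_persons_csv(config$inputs$registry))
    labs <- stage("load", read_labs_csv(config$inputs$labs))
    diagnoses <- stage("load", read_diagnoses_csv(config$inputs$diagnoses))
    roster <- stage("load", read_roster_csv(config$inputs$roster))
  } else {
    config_error("sim/inputs", "config must provide either 'sim' or 'inputs'")
  }

  decisions <- stage("link", link_records(roster, persons, threshold = threshold,
                                          policy = policy, levels = levels))
  stage("link", write_table_csv(decisions, file.path(out_dir, "decisions.csv")))

  plwh <- stage("define-population", select_plwh(persons, labs, window))
  cohort_rost <- stage("define-population", select_cohort(roster, window))
  part <- stage("define-population",
                partition_groups(plwh$eligible, decisions, cohort_rost$eligible))
  stage("define-population", {
    write_table_csv(plwh$eligible[setdiff(names(plwh$eligible), "enrollee")],
                    file.path(out_dir, "eligible.csv"))
    write_table_csv(plwh$exclusions, file.path(out_dir, "exclusions.csv"))
  })

  indicators <- stage("indicators",
                      derive_indicators(plwh$eligible, labs, diagnoses, window))
  stage("indicators", write_table_csv(indicators, file.path(out_dir, "indicators.csv")))

  models <- stage("compare", run_model_suite(indicators, plwh$eligible,
                                             part$group, window))
  artifacts <- list(persons = persons, labs = labs, diagnoses = diagnoses,
                    roster = roster, truth = truth, decisions = decisions,
                    eligible = plwh$eligible, exclusions = plwh$exclusions,
                    cohort_roster = cohort_rost$eligible, group = part$group,
                    indicators = indicators, models = models, window = window)
  tables <- stage("compare", render_tables(artifacts))
  stage("compare", {
    write_table_csv(tables$table2, file.path(out_dir, "table2.csv"))
    write_table_csv(tables$table3, file.path(out_dir, "table3.csv"))
    write_table_csv(tables$table4, file.path(out_dir, "table4.csv"))
  })

  linkage_eval <- if (!is.null(truth)) evaluate_linkage(decisions, truth) else NULL

  manifest <- list(
    package = "cohortlink",
    version = as.character(utils::packageVersion("cohortlink")),
    seed = if (!is.null(config$seed)) config$seed else config$sim$seed,
    flow = list(
      n_registry = nrow(persons),
      n_labs = nrow(labs),
      n_diagnoses = nrow(diagnoses),
      n_roster = nrow(roster),
      n_eligible = nrow(plwh$eligible),
      exclusions = stats::setNames(as.list(plwh$exclusions$n),
                                   plwh$exclusions$criterion),
      n_cohort_roster = nrow(cohort_rost$eligible),
      n_candidate_decisions = nrow(decisions),
      n_accepted = sum(decisions$accepted, na.rm = TRUE),
      n_cohort = nrow(part$cohort),
      n_noncohort = nrow(part$noncohort)
    ),
    linkage = list(threshold = threshold, policy = policy,
                   precision = if (is.null(linkage_eval)) NULL else linkage_eval$precision,
                   recall = if (is.null(linkage_eval)) NULL else linkage_eval$recall)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(c(artifacts, list(tables = tables, linkage_eval = linkage_eval,
                              manifest = manifest)))
}
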