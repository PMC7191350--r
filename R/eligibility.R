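#' Study window definition
#'
#' The analysis windows: the lab/enrollment window (defaults 2011-01-01 to
#' 2016-12-31), the clinical outcome year (2017), and the viral-
#' suppression window (2011-01-01 to 2017-12-31). All intervals are
#' closed.
#'
#' @param lab_start,lab_end lab/enrollment window bounds.
#' @param outcome_year calendar year for care and last-lab suppression.
#' @param supp_start,supp_end ever-suppressed window bounds.
#' @return list of class `"study_window"`.
#' @export
study_window <- function(lab_start = "2011-01-01", lab_end = "2016-12-31",
                         outcome_year = 2017,
                         supp_start = "2011-01-01", supp_end = "2017-12-31") {
  w <- list(lab_start = as.Date(lab_start), lab_end = as.Date(lab_end),
            outcome_year = as.integer(outcome_year),
            supp_start = as.Date(supp_start), supp_end = as.Date(supp_end))
  if (!(w$lab_start < w$lab_end)) {
    config_error("study_window", "lab_start must precede lab_end")
  }
  if (as.integer(format(w$lab_end, "%Y")) >= w$outcome_year) {
    config_error("study_window", "lab window must precede the outcome year end")
  }
  structure(w, class = "study_window")
}

# most recent lab on or before `cutoff` per person; returns a data frame
# person_id, lab_date, jurisdiction_resident
last_lab_before <- function(labs, cutoff) {
  sub <- labs[labs$lab_date <= cutoff, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(person_id = character(0), lab_date = as.Date(character(0)),
                      jurisdiction_resident = logical(0)))
  }
  # stable ordering so ties resolve identically across runs
  sub <- sub[order(sub$person_id, sub$lab_date), , drop = FALSE]
  last <- !duplicated(sub$person_id, fromLast = TRUE)
  sub[last, c("person_id", "lab_date", "jurisdiction_resident"), drop = FALSE]
}

#' Select the surveillance population of people living with HIV
#'
#' Retains persons who (1) have an HIV diagnosis, (2) whose most recent
#' lab on or before the lab-window end falls inside the lab window and
#' carries the jurisdiction-residence flag, and (3) who were alive at the
#' end of the outcome year. Exclusions are tallied by the first failing
#' criterion, so the included count plus all exclusion buckets equals the
#' input count.
#'
#' @param persons registry persons data frame.
#' @param labs labs data frame (`person_id`, `lab_date`,
#'   `jurisdiction_resident`).
#' @param window a [study_window()].
#' @return list with `eligible` (persons subset) and `exclusions`
#'   (data frame `criterion`, `n`).
#' @export
select_plwh <- function(persons, labs, window = study_window()) {
  ll <- last_lab_before(labs, window$lab_end)
  idx <- match(persons$person_id, ll$person_id)
  last_date <- ll$lab_date[idx]
  last_dc <- ll$jurisdiction_resident[idx]

  reason <- rep(NA_character_, nrow(persons))
  reason[is.na(persons$hiv_diagnosis_date)] <- "no_hiv_diagnosis"
  f <- is.na(reason) & is.na(last_date)
  reason[f] <- "no_qualifying_lab"
  f <- is.na(reason) & last_date < window$lab_start
  reason[f] <- "last_lab_before_window"
  f <- is.na(reason) & !last_dc
  reason[f] <- "last_lab_outside_jurisdiction"
  f <- is.na(reason) & persons$vital_status_end_2017 != "alive"
  reason[f] <- "deceased"

  buckets <- c("no_hiv_diagnosis", "no_qualifying_lab", "last_lab_before_window",
               "last_lab_outside_jurisdiction", "deceased")
  tally <- data.frame(
    criterion = c("included", buckets),
    n = c(sum(is.na(reason)),
          vapply(buckets, function(b) sum(reason == b, na.rm = TRUE), integer(1))),
    stringsAsFactors = FALSE
  )
  rownames(tally) <- NULL
  list(eligible = persons[is.na(reason), , drop = FALSE], exclusions = tally)
}

#' Select analysis-eligible cohort roster members
#'
#' Retains roster members with a consent date inside the enrollment window
#' (closed interval), jurisdiction residence, and no withdrawal.
#' Withdrawn members and those with a missing consent date are excluded
#' (and end up analyzed in the non-cohort group).
#'
#' @param roster roster data frame with `consent_date`,
#'   `jurisdiction_resident` and optional `withdrawal_date`.
#' @param window a [study_window()].
#' @return list with `eligible` (roster subset) and `exclusions` tally.
#' @export
select_cohort <- function(roster, window = study_window()) {
  reason <- rep(NA_character_, nrow(roster))
  reason[is.na(roster$consent_date)] <- "missing_consent"
  f <- is.na(reason) & (roster$consent_date < window$lab_start |
                          roster$consent_date > window$lab_end)
  reason[f] <- "consent_outside_window"
  f <- is.na(reason) & !roster$jurisdiction_resident
  reason[f] <- "non_resident"
  if (!is.null(roster$withdrawal_date)) {
    f <- is.na(reason) & !is.na(roster$withdrawal_date)
    reason[f] <- "withdrawn"
  }
  buckets <- c("missing_consent", "consent_outside_window", "non_resident",
               "withdrawn")
  tally <- data.frame(
    criterion = c("included", buckets),
    n = c(sum(is.na(reason)),
          vapply(buckets, function(b) sum(reason == b, na.rm = TRUE), integer(1))),
    stringsAsFactors = FALSE
  )
  rownames(tally) <- NULL
  list(eligible = roster[is.na(reason), , drop = FALSE], exclusions = tally)
}

#' Partition the eligible population into cohort and non-cohort groups
#'
#' The cohort group consists of eligible surveillance persons linked, by
#' an accepted decision, to an analysis-eligible roster member; everyone
#' else is non-cohort. The two groups are disjoint and exhaustive.
#' Accepted decisions referencing persons outside the eligible set are
#' ignored with a message.
#'
#' @param eligible eligible persons data frame from [select_plwh()].
#' @param decisions finalized linkage decisions.
#' @param cohort_roster analysis-eligible roster from [select_cohort()].
#' @return list with `cohort` and `noncohort` persons data frames and
#'   `group`, a named factor over all eligible person ids.
#' @export
partition_groups <- function(eligible, decisions, cohort_roster) {
  acc <- decisions[which(decisions$accepted), , drop = FALSE]
  acc <- acc[acc$roster_id %in% cohort_roster$person_id, , drop = FALSE]
  known <- acc$registry_id %in% eligible$person_id
  if (any(!known)) {
    message(sprintf("partition_groups: %d accepted decision(s) reference non-eligible persons; ignored",
                    sum(!known)))
  }
  cohort_ids <- unique(acc$registry_id[known])
  in_cohort <- eligible$person_id %in% cohort_ids
  group <- factor(ifelse(in_cohort, "cohort", "noncohort"),
                  levels = c("cohort", "noncohort"))
  names(group) <- eligible$person_id
  list(cohort = eligible[in_cohort, , drop = FALSE],
       noncohort = eligible[!in_cohort, , drop = FALSE],
       group = group)
}
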