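#' CDC HIV disease stage from CD4 values
#'
#' Stage 3 (AIDS): CD4 count below 200 cells/µL, CD4 percentage below 14,
#' or a diagnosed AIDS-defining opportunistic infection. Stage 1: CD4
#' count above 500, or (when no count is available) CD4 percentage of 29
#' or more. Stage 2: count between 200 and 500 inclusive, or percentage
#' 14-28 when no count is available. When both a count and a percentage
#' are present, the count takes precedence (CDC convention); with neither
#' input and no opportunistic infection the stage is `"unknown"`.
#'
#' @param cd4_count CD4 count in cells/µL, or `NA`.
#' @param cd4_percent CD4 percentage, or `NA`.
#' @param has_oi logical, any AIDS-defining opportunistic infection.
#' @return character vector over `"1"`, `"2"`, `"3"`, `"unknown"`.
#' @export
classify_stage <- function(cd4_count = NA_real_, cd4_percent = NA_real_,
                           has_oi = FALSE) {
  n <- max(length(cd4_count), length(cd4_percent), length(has_oi))
  cd4_count <- rep_len(cd4_count, n)
  cd4_percent <- rep_len(cd4_percent, n)
  has_oi <- rep_len(has_oi, n)
  out <- rep("unknown", n)
  use_pct <- is.na(cd4_count) & !is.na(cd4_percent)
  out[use_pct & cd4_percent >= 29] <- "1"
  out[use_pct & cd4_percent >= 14 & cd4_percent < 29] <- "2"
  out[use_pct & cd4_percent < 14] <- "3"
  out[!is.na(cd4_count) & cd4_count > 500] <- "1"
  out[!is.na(cd4_count) & cd4_count >= 200 & cd4_count <= 500] <- "2"
  out[!is.na(cd4_count) & cd4_count < 200] <- "3"
  out[has_oi] <- "3"
  out
}

# most recent lab of a given kind on or before `cutoff`; NA if none
latest_value <- function(labs, what, cutoff) {
  sub <- labs[labs$kind == what & labs$lab_date <= cutoff, , drop = FALSE]
  if (nrow(sub) == 0L) return(NA_real_)
  sub$value[which.max(sub$lab_date)]
}

#' Disease stage at the last lab of the outcome period
#'
#' Applies [classify_stage()] to the person's most recent CD4 count and
#' most recent CD4 percentage reported on or before `as_of`, together
#' with any opportunistic-infection diagnosis on or before that date.
#'
#' @param labs one person's labs.
#' @param diagnoses one person's diagnosis events (may be empty).
#' @param as_of cutoff date, default 2017-12-31.
#' @return a single stage label.
#' @export
stage_at_last_lab <- function(labs, diagnoses = NULL, as_of = as.Date("2017-12-31")) {
  has_oi <- !is.null(diagnoses) && nrow(diagnoses) > 0L &&
    any(diagnoses$kind == "oi_aids_defining" & diagnoses$event_date <= as_of)
  classify_stage(latest_value(labs, "cd4_count", as_of),
                 latest_value(labs, "cd4_percent", as_of),
                 has_oi)
}

#' Ever diagnosed with stage 3 (AIDS)
#'
#' TRUE if any CD4 count ever fell below 200 cells/µL, any CD4 percentage
#' below 14, or any AIDS-defining opportunistic infection was diagnosed,
#' regardless of later recovery.
#'
#' @param labs one person's labs.
#' @param diagnoses one person's diagnosis events.
#' @return logical scalar.
#' @export
ever_stage3 <- function(labs, diagnoses = NULL) {
  any(labs$kind == "cd4_count" & labs$value < 200) ||
    any(labs$kind == "cd4_percent" & labs$value < 14) ||
    (!is.null(diagnoses) && any(diagnoses$kind == "oi_aids_defining"))
}

#' Receipt of HIV medical care in a calendar year
#'
#' TRUE if the person has at least one CD4 (count or percentage) or
#' viral-load lab dated within the calendar year, boundaries inclusive.
#'
#' @param labs one person's labs.
#' @param year calendar year.
#' @return logical scalar.
#' @export
received_care <- function(labs, year = 2017) {
  rel <- labs$kind %in% c("cd4_count", "cd4_percent", "viral_load")
  any(rel & format(labs$lab_date, "%Y") == as.character(year))
}

#' Viral-suppression indicators
#'
#' Suppression is a viral load at or below 200 copies/mL (inclusive).
#' Returns: `ever_suppressed`, any suppressed VL within the suppression
#' window; `suppressed_last_lab`, whether the chronologically last VL of
#' the outcome year is suppressed (`NA` when the person has no VL that
#' year); and `suppressed_any`, any suppressed VL in the outcome year.
#'
#' @param labs one person's labs.
#' @param window a [study_window()].
#' @return named list of three logicals (`suppressed_last_lab` may be NA).
#' @export
suppression_indicators <- function(labs, window = study_window()) {
  vl <- labs[labs$kind == "viral_load", , drop = FALSE]
  vl <- vl[order(vl$lab_date), , drop = FALSE]
  ever <- any(vl$lab_date >= window$supp_start & vl$lab_date <= window$supp_end &
                vl$value <= 200)
  in_year <- format(vl$lab_date, "%Y") == as.character(window$outcome_year)
  v17 <- vl[in_year, , drop = FALSE]
  last_lab <- if (nrow(v17) == 0L) NA else v17$value[nrow(v17)] <= 200
  any17 <- nrow(v17) > 0L && any(v17$value <= 200)
  list(ever_suppressed = ever, suppressed_last_lab = last_lab,
       suppressed_any = any17)
}

#' Time from first detectable viral load to first suppression
#'
#' Months (30.4375 days each) between the first VL above 200 copies/mL
#' and the first subsequent VL at or below 200, with category `"0-24"`
#' (inclusive) or `">24"`. Undefined (`NA`) when no detectable VL
#' precedes the first suppressed result.
#'
#' @param labs one person's labs.
#' @return list with `months` and `category` (both possibly `NA`).
#' @export
time_to_suppression <- function(labs) {
  vl <- labs[labs$kind == "viral_load", , drop = FALSE]
  vl <- vl[order(vl$lab_date), , drop = FALSE]
  det <- which(vl$value > 200)
  if (!length(det)) return(list(months = NA_real_, category = NA_character_))
  first_det <- det[1]
  supp <- which(vl$value <= 200 & seq_len(nrow(vl)) > first_det)
  if (!length(supp)) return(list(months = NA_real_, category = NA_character_))
  months <- as.numeric(vl$lab_date[supp[1]] - vl$lab_date[first_det]) / 30.4375
  list(months = months, category = if (months <= 24) "0-24" else ">24")
}

#' Comorbid diagnosis flags within a reporting window
#'
#' One flag per condition (STI; confirmed chronic HBV; confirmed chronic
#' HCV), TRUE if at least one event of that kind is dated within the
#' window (closed interval). Only confirmed chronic hepatitis events are
#' expected in the input — antibody-only records are excluded upstream.
#'
#' @param diagnoses one person's diagnosis events.
#' @param window a [study_window()]; the lab window bounds are used.
#' @return named list of logicals `sti`, `hbv`, `hcv`.
#' @export
comorbidity_flags <- function(diagnoses, window = study_window()) {
  if (is.null(diagnoses) || nrow(diagnoses) == 0L) {
    return(list(sti = FALSE, hbv = FALSE, hcv = FALSE))
  }
  inw <- diagnoses$event_date >= window$lab_start &
    diagnoses$event_date <= window$lab_end
  list(sti = any(inw & diagnoses$kind == "sti"),
       hbv = any(inw & diagnoses$kind == "hbv_chronic_confirmed"),
       hcv = any(inw & diagnoses$kind == "hcv_chronic_confirmed"))
}

#' Derive all continuum indicators, one row per person
#'
#' Applies the stage, care, suppression, time-to-suppression and
#' comorbidity rules to every person and returns the per-person indicator
#' table used by the comparison layer. Also carries the most recent CD4
#' count category (cutoffs 200/500) and the most recent outcome-year CD4
#' count for the descriptive table.
#'
#' @param persons persons data frame (only `person_id` is used).
#' @param labs labs data frame for all persons.
#' @param diagnoses diagnosis events for all persons.
#' @param window a [study_window()].
#' @return data frame with one row per person.
#' @export
derive_indicators <- function(persons, labs, diagnoses, window = study_window()) {
  stage_cutoff <- as.Date(sprintf("%d-12-31", window$outcome_year))
  labs_by <- split(labs, factor(labs$person_id, levels = persons$person_id))
  dx_by <- split(diagnoses, factor(diagnoses$person_id, levels = persons$person_id))

  rows <- lapply(seq_len(nrow(persons)), function(i) {
    lb <- labs_by[[i]]
    dx <- dx_by[[i]]
    sup <- suppression_indicators(lb, window)
    tts <- if (isTRUE(sup$ever_suppressed)) time_to_suppression(lb) else {
      list(months = NA_real_, category = NA_character_)
    }
    com <- comorbidity_flags(dx, window)
    cd4_recent <- latest_value(lb, "cd4_count", stage_cutoff)
    cd4_17 <- {
      sub <- lb[lb$kind == "cd4_count" &
                  format(lb$lab_date, "%Y") == as.character(window$outcome_year), ,
                drop = FALSE]
      if (nrow(sub)) sub$value[which.max(sub$lab_date)] else NA_real_
    }
    data.frame(
      person_id = persons$person_id[i],
      stage_2017 = stage_at_last_lab(lb, dx, stage_cutoff),
      ever_stage3 = ever_stage3(lb, dx),
      care_2017 = received_care(lb, window$outcome_year),
      ever_suppressed = sup$ever_suppressed,
      suppressed_any_2017 = sup$suppressed_any,
      suppressed_last_lab_2017 = sup$suppressed_last_lab,
      tts_months = tts$months,
      tts_category = tts$category,
      cd4_recent = cd4_recent,
      cd4_recent_cat = if (is.na(cd4_recent)) NA_character_ else if (cd4_recent < 200) {
        "<200"
      } else if (cd4_recent <= 500) "200-500" else ">500",
      cd4_2017 = cd4_17,
      sti_2011_2016 = com$sti,
      hbv_2011_2016 = com$hbv,
      hcv_2011_2016 = com$hcv,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
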