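#' Apply identifier corruption to records
#'
#' Simulates real-world identifier noise: missing SSN, a single-character
#' name typo, truncation of a name to a prefix of at least three letters,
#' and an error in exactly one date-of-birth component. Corruptions are
#' applied independently per record, in the fixed order missing SSN, typo,
#' truncation, DOB, so a single RNG seed fully determines the output.
#' Names shorter than three characters are passed through untouched (a
#' message reports how many were skipped).
#'
#' @param records data frame with `first_name`, `last_name`, `dob`, `ssn`.
#' @param rates named list of per-record probabilities `ssn_missing`,
#'   `name_typo`, `name_truncation`, `dob_component_error`.
#' @return the records with corrupted identifiers.
#' @export
corrupt_identifiers <- function(records, rates) {
  for (f in c("ssn_missing", "name_typo", "name_truncation", "dob_component_error")) {
    if (!is_prob(rates[[f]])) config_error(paste0("rates$", f), "must be in [0,1]")
  }
  r <- records
  n <- nrow(r)
  if (n == 0L) return(r)
  skipped <- 0L

  hit <- stats::runif(n) < rates$ssn_missing
  r$ssn[hit] <- ""

  idx <- which(stats::runif(n) < rates$name_typo)
  for (i in idx) {
    f <- if (stats::runif(1) < 0.5) "first_name" else "last_name"
    nm <- r[[f]][i]
    if (is.na(nm) || nchar(nm) < 3L) {
      skipped <- skipped + 1L
      next
    }
    pos <- sample.int(nchar(nm), 1L)
    cur <- substr(nm, pos, pos)
    repl <- sample(setdiff(LETTERS, toupper(cur)), 1L)
    if (cur == tolower(cur)) repl <- tolower(repl)
    substr(nm, pos, pos) <- repl
    r[[f]][i] <- nm
  }

  idx <- which(stats::runif(n) < rates$name_truncation)
  for (i in idx) {
    f <- if (stats::runif(1) < 0.5) "first_name" else "last_name"
    nm <- r[[f]][i]
    if (is.na(nm) || nchar(nm) <= 3L) {
      skipped <- skipped + 1L
      next
    }
    keep <- sample(3:(nchar(nm) - 1L), 1L)
    r[[f]][i] <- substr(nm, 1L, keep)
  }

  idx <- which(stats::runif(n) < rates$dob_component_error)
  for (i in idx) {
    d <- as.POSIXlt(r$dob[i])
    if (is.na(r$dob[i])) next
    comp <- sample(c("day", "month", "year"), 1L)
    day <- d$mday
    mon <- d$mon + 1L
    yr <- d$year + 1900L
    if (comp == "day") {
      day <- sample(setdiff(1:28, day), 1L)
    } else if (comp == "month") {
      repeat {
        m2 <- sample(setdiff(1:12, mon), 1L)
        if (!is.na(as.Date(sprintf("%04d-%02d-%02d", yr, m2, day)))) break
      }
      mon <- m2
    } else {
      repeat {
        y2 <- yr + sample(c(-2L, -1L, 1L, 2L), 1L)
        if (!is.na(as.Date(sprintf("%04d-%02d-%02d", y2, mon, day)))) break
      }
      yr <- y2
    }
    r$dob[i] <- as.Date(sprintf("%04d-%02d-%02d", yr, mon, day))
  }

  if (skipped > 0L) {
    message(sprintf("corrupt_identifiers: %d degenerate short name(s) passed through untouched", skipped))
  }
  r
}

runif_date <- function(n, from, to) {
  a <- as.numeric(as.Date(from))
  b <- as.numeric(as.Date(to))
  as.Date(floor(stats::runif(n, a, b + 1)), origin = "1970-01-01")
}

#' Generate a synthetic surveillance registry
#'
#' Creates a person-level registry with identifiers (names drawn from a
#' bundled static list, unique nine-digit SSNs, dates of birth),
#' demographics drawn from the configured categorical distributions, an
#' HIV diagnosis date on or before the end of the lab window, vital
#' status, longitudinal CD4/viral-load labs with a residence-jurisdiction
#' flag, and STI/HBV/HCV/OI diagnosis events.
#'
#' Each person carries a latent `enrollee` flag drawn with probability
#' `enroll_fraction`; it drives the group-differential clinical simulation
#' (cohort enrollees vs non-enrollees follow the two `outcome_model`
#' probability sets) and determines who [generate_roster()] copies into
#' the cohort roster. Viral-load trajectories follow a two-state
#' detectable/suppressed process: ever-suppressed persons get a
#' suppression-onset date inside the lab window, with a detectable result
#' guaranteed before onset and a suppressed result guaranteed after it;
#' the last outcome-year viral load is suppressed with the configured
#' conditional probability.
#'
#' @param config a [sim_config()].
#' @return list with `persons`, `labs`, `diagnoses` data frames.
#' @export
generate_registry <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  n <- config$n_persons
  ws <- config$study_window[1]
  we <- config$study_window[2]
  outcome_year_start <- as.Date(format(we + 1, "%Y-01-01"))
  outcome_year_end <- as.Date(format(we + 1, "%Y-12-31"))

  persons <- data.frame(
    person_id = sprintf("S%06d", seq_len(n)),
    first_name = sample(cl_first_names, n, replace = TRUE),
    last_name = sample(cl_last_names, n, replace = TRUE),
    ssn = sprintf("%09d", sample.int(899999999L, n) + 100000000L - 1L),
    gender_identity = sample(names(config$demographics$gender_identity), n,
                             replace = TRUE, prob = config$demographics$gender_identity),
    race_ethnicity = sample(names(config$demographics$race_ethnicity), n,
                            replace = TRUE, prob = config$demographics$race_ethnicity),
    transmission_risk = sample(names(config$demographics$transmission_risk), n,
                               replace = TRUE, prob = config$demographics$transmission_risk),
    stringsAsFactors = FALSE
  )
  age_2017 <- pmin(85, pmax(18, stats::rnorm(n, 49, 13)))
  persons$dob <- outcome_year_end - round(age_2017 * 365.25)
  years_since_dx <- pmin(pmax(stats::rgamma(n, shape = 2.25, scale = 10.5 / 2.25), 0.1),
                         age_2017 - 2)
  persons$hiv_diagnosis_date <- we - round(years_since_dx * 365.25)
  persons$vital_status_end_2017 <- ifelse(stats::runif(n) < config$deceased_fraction,
                                          "deceased", "alive")
  persons$jurisdiction_resident <- stats::runif(n) >= config$nonresident_fraction
  persons$enrollee <- stats::runif(n) < config$enroll_fraction
  cd4_setpoint <- stats::rlnorm(n, meanlog = log(560), sdlog = 0.45)

  lab_pid <- list(); lab_date <- list(); lab_kind <- list(); lab_val <- list()
  dx_pid <- list(); dx_date <- list(); dx_kind <- list()
  kinds <- c("viral_load", "cd4_count", "cd4_percent")
  kind_p <- c(0.5, 0.4, 0.1)

  for (i in seq_len(n)) {
    g <- if (persons$enrollee[i]) "cohort" else "noncohort"
    pm <- config$outcome_model[[g]]
    cm <- config$comorbidity_model[[g]]
    care <- stats::runif(1) < pm$care_in_year
    ever <- stats::runif(1) < pm$ever_suppressed

    hs <- max(ws, persons$hiv_diagnosis_date[i])
    k <- stats::rpois(1, config$labs_per_person_mean)
    dts <- sort(runif_date(k, hs, we))
    knd <- sample(kinds, k, replace = TRUE, prob = kind_p)
    if (care) {
      k17 <- 1L + stats::rpois(1, 1)
      d17 <- sort(runif_date(k17, outcome_year_start, outcome_year_end))
      k17nd <- sample(kinds, k17, replace = TRUE, prob = kind_p)
      dts <- c(dts, d17)
      knd <- c(knd, k17nd)
    }

    is_vl <- knd == "viral_load"
    suppressed <- rep(FALSE, length(knd))
    if (ever) {
      span <- max(1, as.numeric(we - hs))
      onset <- hs + sample.int(span, 1L)  # onset in (hs, we]
      suppressed[is_vl] <- dts[is_vl] >= onset
      vl17 <- which(is_vl & dts >= outcome_year_start)
      if (care && length(vl17)) {
        suppressed[vl17[length(vl17)]] <- stats::runif(1) < pm$suppressed_last_lab
      }
      # guarantee the definition-carrying labs exist: one detectable VL
      # before onset, one suppressed VL at/after onset within the window
      pre <- which(is_vl & dts < onset)
      if (!length(pre)) {
        dts <- c(dts, runif_date(1, hs, onset - 1))
        knd <- c(knd, "viral_load")
        suppressed <- c(suppressed, FALSE)
        is_vl <- c(is_vl, TRUE)
      }
      post <- which(is_vl & suppressed)
      if (!length(post)) {
        dts <- c(dts, runif_date(1, onset, we))
        knd <- c(knd, "viral_load")
        suppressed <- c(suppressed, TRUE)
        is_vl <- c(is_vl, TRUE)
      }
    }

    m <- length(knd)
    if (m > 0L) {
      val <- numeric(m)
      vl <- which(is_vl)
      val[vl] <- ifelse(suppressed[vl],
                        round(stats::runif(length(vl), 0, 200)),
                        round(10^stats::runif(length(vl), log10(250), 5.7)))
      cc <- which(knd == "cd4_count")
      val[cc] <- pmax(5, round(stats::rnorm(length(cc), cd4_setpoint[i], 75)))
      cp <- which(knd == "cd4_percent")
      val[cp] <- pmin(60, pmax(1, round(cd4_setpoint[i] / 18 +
                                          stats::rnorm(length(cp), 0, 4))))
      ord <- order(dts)
      lab_pid[[i]] <- rep.int(persons$person_id[i], m)
      lab_date[[i]] <- as.numeric(dts[ord])
      lab_kind[[i]] <- knd[ord]
      lab_val[[i]] <- val[ord]
    }

    ev_kind <- character(0)
    ev_date <- numeric(0)
    if (stats::runif(1) < cm$sti) {
      ev_kind <- c(ev_kind, "sti")
      ev_date <- c(ev_date, as.numeric(runif_date(1, hs, we)))
    }
    if (stats::runif(1) < cm$hbv) {
      ev_kind <- c(ev_kind, "hbv_chronic_confirmed")
      ev_date <- c(ev_date, as.numeric(runif_date(1, hs, we)))
    }
    if (stats::runif(1) < cm$hcv) {
      ev_kind <- c(ev_kind, "hcv_chronic_confirmed")
      ev_date <- c(ev_date, as.numeric(runif_date(1, hs, we)))
    }
    if (stats::runif(1) < config$comorbidity_model$oi) {
      ev_kind <- c(ev_kind, "oi_aids_defining")
      ev_date <- c(ev_date, as.numeric(runif_date(1, persons$hiv_diagnosis_date[i], we)))
    }
    # some pre-window STI history to exercise the window filters
    if (persons$hiv_diagnosis_date[i] <= ws - 400 && stats::runif(1) < 0.03) {
      ev_kind <- c(ev_kind, "sti")
      ev_date <- c(ev_date, as.numeric(runif_date(1, persons$hiv_diagnosis_date[i], ws - 1)))
    }
    if (length(ev_kind)) {
      dx_pid[[i]] <- rep.int(persons$person_id[i], length(ev_kind))
      dx_date[[i]] <- ev_date
      dx_kind[[i]] <- ev_kind
    }
  }

  labs <- data.frame(
    person_id = unlist(lab_pid),
    lab_date = as.Date(unlist(lab_date), origin = "1970-01-01"),
    kind = unlist(lab_kind),
    value = unlist(lab_val),
    stringsAsFactors = FALSE
  )
  labs$jurisdiction_resident <-
    persons$jurisdiction_resident[match(labs$person_id, persons$person_id)]
  diagnoses <- data.frame(
    person_id = unlist(dx_pid),
    event_date = as.Date(unlist(dx_date), origin = "1970-01-01"),
    kind = unlist(dx_kind),
    stringsAsFactors = FALSE
  )
  if (nrow(diagnoses) == 0L) {
    diagnoses <- data.frame(person_id = character(0),
                            event_date = as.Date(character(0)),
                            kind = character(0), stringsAsFactors = FALSE)
  }
  list(persons = persons, labs = labs, diagnoses = diagnoses)
}

#' Generate the cohort enrollment roster from a registry
#'
#' Copies the registry persons flagged as enrollees into a roster with new
#' roster IDs, a consent date inside the enrollment window (on or after
#' HIV diagnosis), an optional withdrawal date, and identifiers passed
#' through [corrupt_identifiers()]. Returns the roster together with the
#' ground-truth identity links for linkage evaluation. Uses its own RNG
#' stream seeded at `config$seed + 1`, so registry and roster are each
#' reproducible from the configuration alone.
#'
#' @param registry_persons the `persons` table from [generate_registry()].
#' @param config the same [sim_config()].
#' @return list with `roster` (data frame) and `truth` (data frame with
#'   `registry_id`, `roster_id`).
#' @export
generate_roster <- function(registry_persons, config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.data.frame(registry_persons) || nrow(registry_persons) == 0L) {
    stop("registry must be a nonempty persons table", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  ws <- config$study_window[1]
  we <- config$study_window[2]
  sel <- which(registry_persons$enrollee)
  src <- registry_persons[sel, , drop = FALSE]
  m <- nrow(src)

  roster <- data.frame(
    person_id = sprintf("C%05d", seq_len(m)),
    first_name = src$first_name,
    last_name = src$last_name,
    dob = src$dob,
    ssn = src$ssn,
    stringsAsFactors = FALSE
  )
  if (m > 0L) {
    consent_from <- pmax(ws, src$hiv_diagnosis_date)
    span <- pmax(1, as.numeric(we - consent_from))
    roster$consent_date <- consent_from +
      floor(stats::runif(m) * (span + 1))
    roster$consent_date <- pmin(roster$consent_date, we)
    withdrew <- stats::runif(m) < config$withdrawal_fraction
    wd <- roster$consent_date +
      ceiling(stats::runif(m) * pmax(1, as.numeric(we - roster$consent_date)))
    roster$withdrawal_date <- as.Date(ifelse(withdrew, wd, NA), origin = "1970-01-01")
    roster$jurisdiction_resident <- src$jurisdiction_resident
    roster <- corrupt_identifiers(roster, config$corruption_rates)
  } else {
    roster$consent_date <- as.Date(character(0))
    roster$withdrawal_date <- as.Date(character(0))
    roster$jurisdiction_resident <- logical(0)
  }
  truth <- data.frame(registry_id = src$person_id,
                      roster_id = roster$person_id,
                      stringsAsFactors = FALSE)
  list(roster = roster, truth = truth)
}
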