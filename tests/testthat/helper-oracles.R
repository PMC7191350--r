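# Independent oracles, written scalar and literal so they share no code
# path with the package implementation.

# --- identifier fixture builders -------------------------------------------

make_ids <- function(first, last, dob, ssn = "", id = NULL) {
  df <- data.frame(first_name = first, last_name = last, dob = as.Date(dob),
                   ssn = ssn, stringsAsFactors = FALSE)
  df$person_id <- if (is.null(id)) sprintf("P%03d", seq_len(nrow(df))) else id
  df
}

small_sim <- function(n = 300, seed = 7, corruption = list(ssn_missing = 0.3,
                                                           name_typo = 0.1,
                                                           name_truncation = 0.1,
                                                           dob_component_error = 0.05),
                      enroll = 0.5, labs_mean = 4) {
  cfg <- sim_config(n_persons = n, enroll_fraction = enroll,
                    corruption_rates = corruption,
                    labs_per_person_mean = labs_mean, seed = seed)
  reg <- generate_registry(cfg)
  ros <- suppressMessages(generate_roster(reg$persons, cfg))
  list(cfg = cfg, registry = reg, roster = ros$roster, truth = ros$truth)
}

# --- brute-force cascade oracle --------------------------------------------

# scalar key-agreement check for one pair at one level, re-deriving the
# slice rules (1-based inclusive, available-prefix, no key when a field is
# missing or the name is shorter than the slice start) directly
oracle_agree <- function(a, b, level) {
  slice <- function(nm, from, to) {
    if (is.na(nm) || nchar(nm) < from) return(NULL)
    substr(nm, from, min(to, nchar(nm)))
  }
  full <- function(nm) if (is.na(nm) || nchar(nm) == 0) NULL else nm
  comp <- function(rec) {
    d <- as.Date(rec$dob)
    day <- if (is.na(d)) NULL else format(d, "%d")
    mon <- if (is.na(d)) NULL else format(d, "%m")
    yr <- if (is.na(d)) NULL else format(d, "%Y")
    dob <- if (is.na(d)) NULL else format(d, "%Y-%m-%d")
    fn <- rec$first_name
    ln <- rec$last_name
    switch(level,
      `1` = if (!is.na(rec$ssn) && rec$ssn != "") list(rec$ssn) else NULL,
      `2` = list(slice(fn, 1, 6), full(ln), dob),
      `3` = list(slice(ln, 1, 1), slice(ln, 3, 8), slice(fn, 2, 8), dob),
      `4` = list(slice(ln, 1, 1), slice(ln, 3, 8), slice(fn, 2, 8), mon, yr),
      `5` = list(slice(ln, 1, 1), slice(ln, 3, 8), slice(fn, 2, 8), day, yr),
      `6` = list(full(ln), slice(fn, 1, 2), dob),
      `7` = list(slice(ln, 1, 3), slice(fn, 1, 3), dob),
      `8` = list(slice(ln, 1, 4), slice(fn, 1, 4), yr),
      `9` = list(slice(fn, 1, 3), slice(ln, 1, 3), mon, yr),
      `10` = list(slice(fn, 1, 3), slice(ln, 1, 3), day, yr),
      `11` = list(slice(fn, 1, 3), slice(ln, 1, 3), mon, yr))
  }
  level <- as.character(level)
  ca <- comp(a)
  cb <- comp(b)
  if (is.null(ca) || is.null(cb)) return(FALSE)
  if (any(vapply(ca, is.null, logical(1))) || any(vapply(cb, is.null, logical(1)))) {
    return(FALSE)
  }
  identical(unlist(ca), unlist(cb))
}

# exhaustive all-pairs, all-levels evaluation: for each roster record the
# minimum level agreeing with ANY registry record, and the candidate set at
# that level
oracle_cascade <- function(roster, registry) {
  res <- lapply(seq_len(nrow(roster)), function(i) {
    a <- as.list(roster[i, ])
    best <- Inf
    cands <- character(0)
    for (j in seq_len(nrow(registry))) {
      b <- as.list(registry[j, ])
      for (lev in 1:11) {
        if (lev > best) break
        if (oracle_agree(a, b, lev)) {
          if (lev < best) {
            best <- lev
            cands <- registry$person_id[j]
          } else {
            cands <- c(cands, registry$person_id[j])
          }
          break
        }
      }
    }
    list(roster_id = roster$person_id[i],
         level = if (is.finite(best)) best else NA_integer_,
         candidates = sort(unique(cands)))
  })
  res
}

# --- from-scratch Pearson chi-square ---------------------------------------

oracle_chisq <- function(m) {
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  stat <- sum((m - e)^2 / e)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}

# --- literal truth-table for CDC disease stage -----------------------------

oracle_stage <- function(count, percent, oi) {
  if (oi) return("3")
  if (!is.na(count)) {
    if (count < 200) return("3")
    if (count <= 500) return("2")
    return("1")
  }
  if (!is.na(percent)) {
    if (percent < 14) return("3")
    if (percent < 29) return("2")
    return("1")
  }
  "unknown"
}

# --- literal suppression rules on a dated VL sequence ----------------------

oracle_suppression <- function(dates, values) {
  dates <- as.Date(dates)
  ord <- order(dates)
  dates <- dates[ord]
  values <- values[ord]
  ever <- any(values <= 200 & dates >= as.Date("2011-01-01") &
                dates <= as.Date("2017-12-31"))
  in17 <- format(dates, "%Y") == "2017"
  last17 <- if (!any(in17)) NA else values[max(which(in17))] <= 200
  any17 <- any(in17 & values <= 200)
  det <- which(values > 200)
  tts <- NA_real_
  if (length(det) > 0) {
    later_supp <- which(values <= 200 & seq_along(values) > det[1])
    if (length(later_supp) > 0) {
      tts <- as.numeric(dates[later_supp[1]] - dates[det[1]]) / 30.4375
    }
  }
  list(ever = ever, last17 = last17, any17 = any17, tts = tts)
}
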