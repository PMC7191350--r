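#' Default agreement weights for the validation score
#'
#' Field weights of the 0-100 validation score that gates final acceptance
#' of candidate links: SSN 40, first name 15, last name 15, birth day /
#' month / year 10 each. The score is an affinely rescaled agreement-weight
#' sum: full agreement on every comparable field scores 100, no agreement
#' scores 0.
#'
#' @return named list of non-negative weights.
#' @export
default_score_weights <- function() {
  list(ssn = 40, first_name = 15, last_name = 15,
       dob_day = 10, dob_month = 10, dob_year = 10)
}

check_weights <- function(weights) {
  need <- names(default_score_weights())
  if (!all(need %in% names(weights))) {
    config_error("weights", paste("must name", paste(need, collapse = ", ")))
  }
  w <- unlist(weights[need])
  if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0) {
    config_error("weights", "must be non-negative and sum to a positive total")
  }
  w
}

# elementwise normalized Levenshtein similarity in [0,1]; 0 when exactly one
# side is empty, NA not expected on normalized input
name_similarity <- function(a, b) {
  m <- pmax(nchar(a), nchar(b))
  d <- mapply(function(x, y) utils::adist(x, y)[1, 1], a, b, USE.NAMES = FALSE)
  ifelse(m == 0, 0, 1 - d / m)
}

# vectorized score over aligned rows of two normalized identifier frames.
# A field enters the denominator only when it is comparable: SSN when both
# present, DOB when both present, a name unless empty on BOTH sides (a
# one-sided blank counts as disagreement).
score_records <- function(a, b, weights = default_score_weights()) {
  w <- check_weights(weights)
  n <- nrow(a)
  num <- numeric(n)
  den <- numeric(n)

  have <- a$ssn != "" & b$ssn != ""
  num <- num + w["ssn"] * (have & a$ssn == b$ssn)
  den <- den + w["ssn"] * have

  for (f in c("first_name", "last_name")) {
    ax <- a[[f]]
    bx <- b[[f]]
    have <- nzchar(ax) | nzchar(bx)
    sim <- name_similarity(ax, bx)
    num <- num + w[f] * ifelse(have, sim, 0)
    den <- den + w[f] * have
  }

  da <- as.Date(a$dob)
  db <- as.Date(b$dob)
  have <- !is.na(da) & !is.na(db)
  for (cmp in c("dob_day", "dob_month", "dob_year")) {
    fmt <- c(dob_day = "%d", dob_month = "%m", dob_year = "%Y")[[cmp]]
    agree <- have & format(da, fmt) == format(db, fmt)
    agree[is.na(agree)] <- FALSE
    num <- num + w[cmp] * agree
    den <- den + w[cmp] * have
  }

  unname(ifelse(den > 0, 100 * num / den, 0))
}

#' Validation score for one pair of identifier records
#'
#' Weighted field-agreement score on a 0-100 scale: exact SSN agreement,
#' normalized edit-distance similarity for each name, and exact agreement
#' on each date-of-birth component, rescaled over the comparable fields so
#' that full agreement gives 100 and none gives 0. Symmetric in its two
#' arguments and monotone non-decreasing in each field's agreement.
#'
#' @param a,b normalized identifier records (one-row data frames or lists
#'   with `first_name`, `last_name`, `dob`, `ssn`).
#' @param weights field weights, see [default_score_weights()].
#' @return a single numeric score in \[0, 100\].
#' @export
score_pair <- function(a, b, weights = default_score_weights()) {
  as1 <- as.data.frame(a[c("first_name", "last_name", "dob", "ssn")])
  bs1 <- as.data.frame(b[c("first_name", "last_name", "dob", "ssn")])
  score_records(as1, bs1, weights)
}

#' Deterministic match-key cascade
#'
#' Compares every roster record against the registry with the 11-level
#' match-key cascade: a roster record's assigned level is the lowest level
#' at which its key is defined and agrees with at least one registry
#' record's key; all registry records sharing that winning key become
#' candidate decisions (ties are resolved later by
#' [resolve_duplicates()]). Records with no key agreement at any level get
#' `registry_id = NA`. Output order is sorted by roster then registry id,
#' so results do not depend on input row order.
#'
#' @param roster,registry data frames with `person_id` plus the identifier
#'   columns `first_name`, `last_name`, `dob`, `ssn`, already normalized
#'   (see [normalize_identifiers()]). Registry `person_id`s must be unique.
#' @param weights score weights passed to the validation score.
#' @param levels integer vector of cascade levels to use (default all 11);
#'   restricting to `1:2` reproduces an exact-identifier-only match.
#' @return data frame of candidate decisions with columns `roster_id`,
#'   `registry_id`, `key_level`, `score`, `review_flag`, `accepted` (NA,
#'   set by [apply_review_policy()]) and `elimination_reason`.
#' @export
cascade_match <- function(roster, registry, weights = default_score_weights(),
                          levels = 1:11) {
  stopifnot(is.data.frame(roster), is.data.frame(registry))
  if (anyDuplicated(registry$person_id)) {
    stop("registry person_id values must be unique", call. = FALSE)
  }
  if (!all(levels %in% 1:11)) {
    stop("'levels' must be a subset of 1:11", call. = FALSE)
  }
  levels <- sort(unique(as.integer(levels)))
  if (11L %in% levels && 9L %in% levels) {
    message("match key 11 is identical to key 9 as specified; level 11 is unreachable")
  }

  n_ros <- nrow(roster)
  pending <- seq_len(n_ros)
  pair_ri <- integer(0)
  pair_gi <- integer(0)
  pair_lev <- integer(0)

  for (lev in levels) {
    if (!length(pending)) break
    gkey <- build_match_key(registry, lev)
    rkey <- build_match_key(roster, lev)
    ok <- rkey[pending]
    hit <- !is.na(ok) & ok %in% gkey[!is.na(gkey)]
    if (any(hit)) {
      idx <- pending[hit]
      bykey <- split(seq_len(nrow(registry)), gkey)
      for (i in idx) {
        gis <- bykey[[rkey[i]]]
        pair_ri <- c(pair_ri, rep.int(i, length(gis)))
        pair_gi <- c(pair_gi, gis)
        pair_lev <- c(pair_lev, rep.int(lev, length(gis)))
      }
      pending <- pending[!hit]
    }
  }

  id_cols <- c("first_name", "last_name", "dob", "ssn")
  matched <- data.frame(
    roster_id = roster$person_id[pair_ri],
    registry_id = registry$person_id[pair_gi],
    key_level = pair_lev,
    score = if (length(pair_ri)) {
      score_records(roster[pair_ri, id_cols], registry[pair_gi, id_cols], weights)
    } else numeric(0),
    stringsAsFactors = FALSE
  )
  unmatched <- data.frame(
    roster_id = roster$person_id[pending],
    registry_id = rep(NA_character_, length(pending)),
    key_level = rep(NA_integer_, length(pending)),
    score = rep(NA_real_, length(pending)),
    stringsAsFactors = FALSE
  )
  out <- rbind(matched, unmatched)
  out$review_flag <- !is.na(out$key_level) & out$key_level >= 7L
  out$accepted <- NA
  out$elimination_reason <- "none"
  out <- out[order(out$roster_id, out$registry_id, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enforce one-to-one linkage among candidate decisions
#'
#' Deduplicates candidate decisions so that each roster record and each
#' registry record survives in at most one link. Among decisions competing
#' for the same person on either side, the survivor is chosen by lowest
#' key level, then highest score, then lowest registry id (then lowest
#' roster id) — a deterministic order independent of input arrangement.
#' Losers are retained with `elimination_reason = "duplicate_loser"`.
#'
#' @param decisions data frame from [cascade_match()].
#' @return the same data frame with `elimination_reason` updated.
#' @export
resolve_duplicates <- function(decisions) {
  d <- decisions
  cand <- which(!is.na(d$registry_id))
  if (!length(cand)) return(d)
  ord <- cand[order(d$key_level[cand], -d$score[cand],
                    d$registry_id[cand], d$roster_id[cand])]
  used <- new.env(hash = TRUE, parent = emptyenv())
  for (i in ord) {
    rk <- paste0("R:", d$roster_id[i])
    gk <- paste0("G:", d$registry_id[i])
    if (is.null(used[[rk]]) && is.null(used[[gk]])) {
      used[[rk]] <- TRUE
      used[[gk]] <- TRUE
    } else {
      d$elimination_reason[i] <- "duplicate_loser"
    }
  }
  d
}

#' Apply the review policy and score threshold
#'
#' Finalizes candidate decisions. Matches made through the partial-name
#' keys (levels 7-11) carry `review_flag = TRUE`; in the source workflow
#' these went to manual review, modeled here as an explicit policy:
#' `"auto_reject"` eliminates all review-flagged decisions
#' (`elimination_reason = "manual_review"`), while `"score_gate"` (the
#' default) and `"auto_accept"` retain them. Independently of the policy,
#' the validation score gates every surviving decision: a score below
#' `threshold` eliminates it (`"below_threshold"`). A decision is
#' `accepted` when it is matched, survived deduplication and review, and
#' scored at or above the threshold.
#'
#' @param decisions data frame from [resolve_duplicates()].
#' @param policy one of `"score_gate"`, `"auto_accept"`, `"auto_reject"`.
#' @param threshold acceptance score threshold, default 80.
#' @return the decisions data frame with `accepted` and
#'   `elimination_reason` finalized.
#' @export
apply_review_policy <- function(decisions, policy = c("score_gate", "auto_accept",
                                                      "auto_reject"),
                                threshold = 80) {
  if (!is.character(policy) || !all(policy %in% c("score_gate", "auto_accept",
                                                  "auto_reject"))) {
    config_error("policy", "must be one of score_gate, auto_accept, auto_reject")
  }
  policy <- match.arg(policy)
  d <- decisions
  d$review_flag <- !is.na(d$key_level) & d$key_level >= 7L
  live <- !is.na(d$registry_id) & d$elimination_reason == "none"
  if (policy == "auto_reject") {
    kill <- live & d$review_flag
    d$elimination_reason[kill] <- "manual_review"
    live <- live & !kill
  }
  below <- live & d$score < threshold
  d$elimination_reason[below] <- "below_threshold"
  d$accepted <- !is.na(d$registry_id) & d$elimination_reason == "none" &
    d$score >= threshold
  d
}

#' Run the full linkage stage
#'
#' Convenience wrapper: normalize both sides, run [cascade_match()],
#' [resolve_duplicates()] and [apply_review_policy()].
#'
#' @param roster,registry data frames with `person_id` and raw identifier
#'   columns.
#' @param threshold acceptance score threshold.
#' @param policy review policy, see [apply_review_policy()].
#' @param weights score weights.
#' @param levels cascade levels to use.
#' @return finalized decisions data frame.
#' @export
link_records <- function(roster, registry, threshold = 80,
                         policy = "score_gate",
                         weights = default_score_weights(), levels = 1:11) {
  ros <- normalize_identifiers(roster)
  reg <- normalize_identifiers(registry)
  d <- cascade_match(ros, reg, weights = weights, levels = levels)
  d <- resolve_duplicates(d)
  apply_review_policy(d, policy = policy, threshold = threshold)
}

#' Evaluate linkage decisions against known ground truth
#'
#' @param decisions finalized decisions data frame.
#' @param truth data frame of true links with columns `registry_id`,
#'   `roster_id` (synthetic runs only).
#' @return list with `precision` (true accepted / accepted; `NA` with a
#'   warning when nothing was accepted), `recall` (true accepted / number
#'   of true links; `NA` with a warning when truth is empty),
#'   `true_positives`, `n_accepted`, `n_truth`, and `by_level`, the
#'   histogram of accepted decisions over key levels 1-11.
#' @export
evaluate_linkage <- function(decisions, truth) {
  acc <- decisions[which(decisions$accepted), , drop = FALSE]
  truth_keys <- paste(truth$registry_id, truth$roster_id, sep = "\r")
  acc_keys <- paste(acc$registry_id, acc$roster_id, sep = "\r")
  tp <- sum(acc_keys %in% truth_keys)
  precision <- if (nrow(acc) > 0) tp / nrow(acc) else {
    warning("no accepted decisions; precision undefined")
    NA_real_
  }
  recall <- if (nrow(truth) > 0) tp / nrow(truth) else {
    warning("empty ground truth; recall undefined")
    NA_real_
  }
  list(precision = precision, recall = recall, true_positives = tp,
       n_accepted = nrow(acc), n_truth = nrow(truth),
       by_level = table(factor(acc$key_level, levels = 1:11)))
}
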