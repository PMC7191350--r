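test_that("validation score spans 0 to 100 with the stated boundary cases", {
  a <- normalize_identifiers(make_ids("Mary", "Jones", "1980-01-01", "111111111"))
  expect_equal(score_pair(a, a), 100)
  # zero positional character overlap on both names, all DOB components and
  # the SSN disagree
  b <- normalize_identifiers(make_ids("Qqqq", "Zzzzz", "1955-12-31", "999999999"))
  expect_equal(score_pair(a, b), 0)
  # partial agreement is strictly between
  c1 <- normalize_identifiers(make_ids("Mary", "Jones", "1980-01-01", "999999999"))
  s <- score_pair(a, c1)
  expect_gt(s, 0)
  expect_lt(s, 100)
  # missing SSN on one side drops the field rather than penalizing it
  c2 <- normalize_identifiers(make_ids("Mary", "Jones", "1980-01-01", ""))
  expect_equal(score_pair(a, c2), 100)
  expect_error(score_pair(a, b, weights = list(ssn = 0, first_name = 0,
                                               last_name = 0, dob_day = 0,
                                               dob_month = 0, dob_year = 0)),
               "configuration")
})

test_that("the score is symmetric over many random pairs", {
  sim <- small_sim(n = 500, seed = 41, enroll = 1)
  a <- normalize_identifiers(sim$registry$persons)
  b <- normalize_identifiers(sim$roster)
  set.seed(42)
  i <- sample(nrow(a), 1000, replace = TRUE)
  j <- sample(nrow(b), 1000, replace = TRUE)
  cols <- c("first_name", "last_name", "dob", "ssn")
  s_ab <- cohortlink:::score_records(a[i, cols], b[j, cols])
  s_ba <- cohortlink:::score_records(b[j, cols], a[i, cols])
  expect_equal(s_ab, s_ba, tolerance = 1e-12)
  expect_true(all(s_ab >= 0 & s_ab <= 100))
})

test_that("the score is monotone in per-field agreement", {
  base <- normalize_identifiers(make_ids("Mary", "Jones", "1980-01-01", "111111111"))
  far <- normalize_identifiers(make_ids("Zork", "Quux", "1955-12-31", "999999999"))
  # flipping each field of `far` to agree with `base` never lowers the score
  s0 <- score_pair(base, far)
  for (f in c("first_name", "last_name", "dob", "ssn")) {
    closer <- far
    closer[[f]] <- base[[f]]
    expect_gte(score_pair(base, closer), s0)
  }
  # partial name agreement scores between none and full
  mid <- far
  mid$first_name <- "MARD"  # edit distance 2 from MARY
  expect_gt(score_pair(base, mid), s0)
  expect_lt(score_pair(base, mid), score_pair(base, {
    x <- far; x$first_name <- "MARY"; x
  }))
})

test_that("deduplication enforces one-to-one links with the stated tie-breaks", {
  d <- data.frame(
    roster_id = c("C1", "C2", "C3", "C3"),
    registry_id = c("S1", "S1", "S2", "S3"),
    key_level = c(2L, 7L, 4L, 4L),
    score = c(90, 95, 88, 88),
    review_flag = FALSE, accepted = NA, elimination_reason = "none",
    stringsAsFactors = FALSE)
  out <- resolve_duplicates(d)
  # level precedence: C1 at level 2 beats C2 at level 7 for S1
  expect_identical(out$elimination_reason[out$roster_id == "C1"], "none")
  expect_identical(out$elimination_reason[out$roster_id == "C2"], "duplicate_loser")
  # tie on level and score: lowest registry id survives
  expect_identical(out$elimination_reason[out$roster_id == "C3" &
                                            out$registry_id == "S2"], "none")
  expect_identical(out$elimination_reason[out$roster_id == "C3" &
                                            out$registry_id == "S3"], "duplicate_loser")
})

test_that("surviving links are one-to-one on synthetic data", {
  sim <- small_sim(n = 250, seed = 43,
                   corruption = list(ssn_missing = 0.6, name_typo = 0.2,
                                     name_truncation = 0.2,
                                     dob_component_error = 0.1))
  d <- suppressMessages(link_records(sim$roster, sim$registry$persons))
  acc <- d[which(d$accepted), ]
  expect_identical(anyDuplicated(acc$roster_id), 0L)
  expect_identical(anyDuplicated(acc$registry_id), 0L)
})

test_that("review policies and the score threshold finalize decisions as specified", {
  d <- data.frame(
    roster_id = c("C1", "C2", "C3"),
    registry_id = c("S1", "S2", "S3"),
    key_level = c(3L, 8L, 9L),
    score = c(95, 92, 79.9),
    review_flag = FALSE, accepted = NA, elimination_reason = "none",
    stringsAsFactors = FALSE)
  out <- apply_review_policy(d, policy = "score_gate", threshold = 80)
  expect_identical(out$review_flag, c(FALSE, TRUE, TRUE))
  expect_true(out$accepted[1])
  expect_true(out$accepted[2])
  expect_false(out$accepted[3])
  expect_identical(out$elimination_reason[3], "below_threshold")

  rej <- apply_review_policy(d, policy = "auto_reject", threshold = 80)
  expect_false(rej$accepted[2])
  expect_identical(rej$elimination_reason[2], "manual_review")
  expect_identical(rej$elimination_reason[3], "manual_review")
  expect_true(rej$accepted[1])

  expect_error(apply_review_policy(d, policy = "ask_a_friend"), "configuration")
})

test_that("linkage evaluation handles perfect, empty and degenerate cases", {
  truth <- data.frame(registry_id = c("S1", "S2"), roster_id = c("C1", "C2"),
                      stringsAsFactors = FALSE)
  d <- data.frame(roster_id = c("C1", "C2"), registry_id = c("S1", "S2"),
                  key_level = 1L, score = 100, review_flag = FALSE,
                  accepted = TRUE, elimination_reason = "none",
                  stringsAsFactors = FALSE)
  ev <- evaluate_linkage(d, truth)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_identical(unname(ev$by_level["1"]), 2L)

  d$accepted <- FALSE
  expect_warning(ev2 <- evaluate_linkage(d, truth), "precision")
  expect_true(is.na(ev2$precision))
  expect_equal(ev2$recall, 0)

  expect_warning(ev3 <- evaluate_linkage(d, truth[0, ]), "recall|truth")
  expect_true(is.na(ev3$recall))
})
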