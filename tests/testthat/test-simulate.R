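test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_persons = 0), "n_persons")
  expect_error(sim_config(enroll_fraction = 1.2), "enroll_fraction")
  expect_error(sim_config(corruption_rates = list(ssn_missing = -0.1,
                                                  name_typo = 0, name_truncation = 0,
                                                  dob_component_error = 0)),
               "ssn_missing")
  expect_error(sim_config(labs_per_person_mean = 0), "labs_per_person_mean")
  expect_error(sim_config(study_window = c("2016-12-31", "2011-01-01")),
               "study_window")
})

test_that("a fixed seed reproduces registry and roster exactly", {
  cfg <- sim_config(n_persons = 100, seed = 7)
  a <- generate_registry(cfg)
  b <- generate_registry(cfg)
  expect_identical(a, b)
  ra <- suppressMessages(generate_roster(a$persons, cfg))
  rb <- suppressMessages(generate_roster(b$persons, cfg))
  expect_identical(ra, rb)
})

test_that("lab counts follow the configured Poisson mean", {
  # outcome probabilities zero so no care-year or suppression labs are
  # added and the history Poisson law is observed directly
  cfg <- sim_config(
    n_persons = 10000, labs_per_person_mean = 3, seed = 11,
    outcome_model = list(
      cohort = list(care_in_year = 0, ever_suppressed = 0, suppressed_last_lab = 0),
      noncohort = list(care_in_year = 0, ever_suppressed = 0, suppressed_last_lab = 0)))
  reg <- generate_registry(cfg)
  mean_labs <- nrow(reg$labs) / cfg$n_persons
  se <- sqrt(3 / cfg$n_persons)
  expect_lt(abs(mean_labs - 3), 3 * se)
})

test_that("roster size is binomial in the enrollment fraction", {
  cfg <- sim_config(n_persons = 10000, enroll_fraction = 0.4, seed = 3)
  reg <- generate_registry(cfg)
  ros <- suppressMessages(generate_roster(reg$persons, cfg))
  se <- sqrt(10000 * 0.4 * 0.6)
  expect_lt(abs(nrow(ros$roster) - 4000), 3 * se)
  expect_identical(nrow(ros$truth), nrow(ros$roster))
  expect_false(anyDuplicated(ros$truth$roster_id) > 0)
})

test_that("zero enrollment yields an empty roster and empty ground truth", {
  cfg <- sim_config(n_persons = 50, enroll_fraction = 0, seed = 5)
  reg <- generate_registry(cfg)
  ros <- generate_roster(reg$persons, cfg)
  expect_identical(nrow(ros$roster), 0L)
  expect_identical(nrow(ros$truth), 0L)
  expect_error(generate_roster(reg$persons[0, ], cfg), "nonempty")
})

test_that("full enrollment with no corruption copies identifiers verbatim", {
  cfg <- sim_config(n_persons = 80, enroll_fraction = 1,
                    corruption_rates = list(ssn_missing = 0, name_typo = 0,
                                            name_truncation = 0,
                                            dob_component_error = 0),
                    seed = 9)
  reg <- generate_registry(cfg)
  ros <- generate_roster(reg$persons, cfg)
  src <- reg$persons[match(ros$truth$registry_id, reg$persons$person_id), ]
  for (f in c("first_name", "last_name", "dob", "ssn")) {
    expect_identical(ros$roster[[f]], src[[f]])
  }
})

test_that("corruption operators behave as specified", {
  recs <- make_ids(rep("Margaret", 400), rep("Johnson", 400),
                   rep("1980-05-02", 400), sprintf("%09d", 1:400))

  zero <- list(ssn_missing = 0, name_typo = 0, name_truncation = 0,
               dob_component_error = 0)
  expect_identical(corrupt_identifiers(recs, zero), recs)

  out <- corrupt_identifiers(recs, modifyList(zero, list(ssn_missing = 1)))
  expect_true(all(out$ssn == ""))
  expect_identical(out$first_name, recs$first_name)
  expect_identical(out$dob, recs$dob)

  set.seed(31)
  out <- corrupt_identifiers(recs, modifyList(zero, list(dob_component_error = 1)))
  diffs <- mapply(function(a, b) {
    a <- as.POSIXlt(a); b <- as.POSIXlt(b)
    sum(c(a$mday != b$mday, a$mon != b$mon, a$year != b$year))
  }, recs$dob, out$dob)
  expect_true(all(diffs == 1))

  set.seed(77)
  big <- make_ids(rep("Margaret", 10000), rep("Johnson", 10000),
                  rep("1980-05-02", 10000), "")
  out <- corrupt_identifiers(big, modifyList(zero, list(name_typo = 0.5)))
  frac <- mean(out$first_name != big$first_name | out$last_name != big$last_name)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))

  set.seed(78)
  out <- corrupt_identifiers(big, modifyList(zero, list(name_truncation = 1)))
  trunc_len <- ifelse(out$first_name != big$first_name, nchar(out$first_name),
                      nchar(out$last_name))
  expect_true(all(trunc_len >= 3))
  expect_true(all(out$first_name == substr(big$first_name, 1, nchar(out$first_name))))

  # degenerate short names pass through untouched, with a log message
  short <- make_ids(c("Al", "Bo"), c("Ng", "Wu"), "1990-01-01", "")
  expect_message(
    out <- corrupt_identifiers(short, modifyList(zero, list(name_typo = 1))),
    "degenerate")
  expect_identical(out$first_name, short$first_name)
})

test_that("registry and roster round-trip losslessly through the CSV layer", {
  sim <- small_sim(n = 60, seed = 13)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "registry.csv")
  p2 <- file.path(d, "roster.csv")
  p3 <- file.path(d, "labs.csv")
  write_table_csv(sim$registry$persons, p1)
  write_table_csv(sim$roster, p2)
  write_table_csv(sim$registry$labs, p3)
  back <- read_persons_csv(p1)
  expect_identical(back, sim$registry$persons)
  expect_identical(read_roster_csv(p2), sim$roster)
  expect_identical(read_labs_csv(p3), sim$registry$labs)
})
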