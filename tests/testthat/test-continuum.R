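lab_rows <- function(dates, kinds, values, id = "P1", dc = TRUE) {
  data.frame(person_id = id, lab_date = as.Date(dates), kind = kinds,
             value = values, jurisdiction_resident = dc, stringsAsFactors = FALSE)
}
vl_rows <- function(dates, values, id = "P1") {
  lab_rows(dates, "viral_load", values, id)
}

test_that("stage classification follows the CDC thresholds with count precedence", {
  expect_identical(classify_stage(150), "3")
  expect_identical(classify_stage(501), "1")
  expect_identical(classify_stage(500), "2")
  expect_identical(classify_stage(200), "2")
  expect_identical(classify_stage(199), "3")
  expect_identical(classify_stage(650, 12), "1")      # count precedence
  expect_identical(classify_stage(NA, 12), "3")
  expect_identical(classify_stage(NA, 14), "2")
  expect_identical(classify_stage(NA, 28), "2")
  expect_identical(classify_stage(NA, 29), "1")
  expect_identical(classify_stage(650, has_oi = TRUE), "3")
  expect_identical(classify_stage(NA, NA, FALSE), "unknown")
})

test_that("stage in the outcome year uses the last reported CD4 values", {
  expect_identical(stage_at_last_lab(vl_rows("2017-01-01", 50)), "unknown")
  labs <- lab_rows(c("2016-06-01", "2017-06-01"), "cd4_count", c(550, 180))
  expect_identical(stage_at_last_lab(labs), "3")
  labs2 <- lab_rows(c("2016-06-01", "2017-06-01"), "cd4_count", c(180, 550))
  expect_identical(stage_at_last_lab(labs2), "1")
  # labs after the cutoff are ignored
  labs3 <- lab_rows(c("2017-06-01", "2018-03-01"), "cd4_count", c(550, 100))
  expect_identical(stage_at_last_lab(labs3), "1")
})

test_that("ever-stage-3 is a lifetime indicator and is monotone in history", {
  labs <- lab_rows(c("2012-01-01", "2014-01-01"), "cd4_count", c(199, 700))
  expect_true(ever_stage3(labs))
  labs2 <- lab_rows("2014-01-01", "cd4_count", 250)
  expect_false(ever_stage3(labs2))
  oi <- data.frame(person_id = "P1", event_date = as.Date("2013-01-01"),
                   kind = "oi_aids_defining", stringsAsFactors = FALSE)
  expect_true(ever_stage3(labs2[0, ], oi))
  # adding history can only turn it on, never off
  expect_true(ever_stage3(rbind(labs2, labs), NULL))
})

test_that("receipt of care counts only CD4/VL labs in the calendar year, boundaries inclusive", {
  expect_true(received_care(vl_rows("2017-12-31", 50), 2017))
  expect_true(received_care(lab_rows("2017-01-01", "cd4_percent", 25), 2017))
  expect_false(received_care(vl_rows("2016-12-31", 50), 2017))
})

test_that("suppression indicators distinguish last-lab from any-lab in the outcome year", {
  s <- suppression_indicators(vl_rows("2015-01-01", 200))
  expect_true(s$ever_suppressed)             # threshold is inclusive
  expect_true(is.na(s$suppressed_last_lab))  # no outcome-year VL

  s2 <- suppression_indicators(vl_rows(c("2017-03-01", "2017-11-01"), c(50000, 40)))
  expect_true(s2$suppressed_last_lab)
  expect_true(s2$suppressed_any)

  s3 <- suppression_indicators(vl_rows(c("2017-03-01", "2017-11-01"), c(40, 50000)))
  expect_false(s3$suppressed_last_lab)
  expect_true(s3$suppressed_any)

  # pre-window suppression does not count as ever suppressed
  s4 <- suppression_indicators(vl_rows("2009-01-01", 40))
  expect_false(s4$ever_suppressed)
})

test_that("time to suppression runs from first detectable to first subsequent suppressed VL", {
  t1 <- time_to_suppression(vl_rows(c("2012-01-01", "2012-07-01"), c(10000, 40)))
  expect_equal(t1$months, 182 / 30.4375, tolerance = 1e-10)
  expect_identical(t1$category, "0-24")

  t2 <- time_to_suppression(vl_rows(c("2011-01-01", "2014-01-01"), c(10000, 40)))
  expect_gt(t2$months, 24)
  expect_identical(t2$category, ">24")

  # first-ever VL already suppressed: undefined
  t3 <- time_to_suppression(vl_rows(c("2012-01-01", "2013-01-01"), c(80, 90)))
  expect_true(is.na(t3$months))
  expect_true(is.na(t3$category))
})

test_that("comorbidity flags respect the 2011-2016 reporting window", {
  dx <- data.frame(
    person_id = "P1",
    event_date = as.Date(c("2010-05-01", "2013-02-01")),
    kind = c("sti", "hcv_chronic_confirmed"), stringsAsFactors = FALSE)
  fl <- comorbidity_flags(dx)
  expect_false(fl$sti)   # 2010 only
  expect_true(fl$hcv)
  expect_false(fl$hbv)
})

test_that("indicator implications hold on synthetic data", {
  sim <- small_sim(n = 400, seed = 61)
  ind <- derive_indicators(sim$registry$persons, sim$registry$labs,
                           sim$registry$diagnoses)
  # a defined last-lab suppression status implies care in the outcome year
  expect_true(all(ind$care_2017[!is.na(ind$suppressed_last_lab_2017)]))
  # any-lab suppression in the outcome year implies ever suppressed
  expect_true(all(ind$ever_suppressed[ind$suppressed_any_2017]))
  # time-to-suppression category defined only for the ever suppressed
  expect_true(all(ind$ever_suppressed[!is.na(ind$tts_category)]))
})

test_that("group prevalences recover the configured outcome model", {
  cfg <- sim_config(n_persons = 8000, seed = 63,
                    corruption_rates = list(ssn_missing = 0, name_typo = 0,
                                            name_truncation = 0,
                                            dob_component_error = 0))
  reg <- generate_registry(cfg)
  ind <- derive_indicators(reg$persons, reg$labs, reg$diagnoses)
  enr <- reg$persons$enrollee[match(ind$person_id, reg$persons$person_id)]
  for (grp in c("cohort", "noncohort")) {
    pm <- cfg$outcome_model[[grp]]
    sel <- if (grp == "cohort") enr else !enr
    n <- sum(sel)
    care_hat <- mean(ind$care_2017[sel])
    expect_lt(abs(care_hat - pm$care_in_year),
              3 * sqrt(pm$care_in_year * (1 - pm$care_in_year) / n))
    ever_hat <- mean(ind$ever_suppressed[sel])
    expect_lt(abs(ever_hat - pm$ever_suppressed),
              3 * sqrt(pm$ever_suppressed * (1 - pm$ever_suppressed) / n))
    # last-lab suppression, conditional as defined by the generator
    cond <- sel & ind$care_2017 & ind$ever_suppressed &
      !is.na(ind$suppressed_last_lab_2017)
    m <- sum(cond)
    last_hat <- mean(ind$suppressed_last_lab_2017[cond])
    expect_lt(abs(last_hat - pm$suppressed_last_lab),
              3 * sqrt(pm$suppressed_last_lab * (1 - pm$suppressed_last_lab) / m))
  }
})
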