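#' Cross-tabulate a categorical variable against study groups
#'
#' Builds the counts and one-decimal column percentages (round half-up,
#' denominators = non-missing column totals) for one characteristic, and
#' attaches the Pearson chi-square test. Degenerate tables (a single
#' category, or an empty group) are returned without a test, with a
#' warning.
#'
#' @param values character/factor vector of the characteristic, aligned
#'   with `group`; `NA`s are dropped unless the variable codes its own
#'   missing category (e.g. "Not identified").
#' @param group factor with the group labels (e.g. cohort / noncohort).
#' @param variable display name of the characteristic.
#' @param categories optional explicit category order.
#' @return list of class `"cl_contingency"`: `variable`, `counts`, `pct`
#'   (matrices categories x groups), `statistic`, `df`, `p_value`.
#' @export
build_table <- function(values, group, variable = "characteristic",
                        categories = NULL) {
  stopifnot(length(values) == length(group))
  keep <- !is.na(values) & !is.na(group)
  values <- as.character(values)[keep]
  group <- droplevels(as.factor(group[keep]))
  if (is.null(categories)) categories <- sort(unique(values))
  counts <- table(factor(values, levels = categories), group)
  counts <- unclass(counts)
  totals <- colSums(counts)
  pct <- sweep(counts, 2, pmax(totals, 1), function(n, d) percent_1dp(n, d))
  test <- if (nrow(counts) >= 2 && ncol(counts) >= 2 && all(totals > 0) &&
              all(rowSums(counts) > 0)) {
    chi_square(counts)
  } else {
    warning(sprintf("table '%s' is degenerate; chi-square test skipped", variable))
    list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  }
  structure(list(variable = variable, counts = counts, pct = pct,
                 totals = totals, statistic = test$statistic, df = test$df,
                 p_value = test$p_value),
            class = "cl_contingency")
}

#' Pearson chi-square test of homogeneity
#'
#' Pearson statistic over an r x c count matrix with expected counts from
#' the row/column margins, df = (r-1)(c-1), upper-tail p-value. No
#' continuity correction (matching standard surveillance reporting).
#'
#' @param counts matrix of non-negative counts, at least 2 x 2.
#' @return list `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("chi-square requires at least 2 rows and 2 columns", call. = FALSE)
  }
  label <- function(nms, i) if (is.null(nms)) as.character(i) else nms[i]
  if (any(rowSums(counts) == 0)) {
    i <- which(rowSums(counts) == 0)[1]
    stop(sprintf("degenerate margin: row '%s' has zero total",
                 label(rownames(counts), i)), call. = FALSE)
  }
  if (any(colSums(counts) == 0)) {
    i <- which(colSums(counts) == 0)[1]
    stop(sprintf("degenerate margin: column '%s' has zero total",
                 label(colnames(counts), i)), call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' One-way ANOVA for a continuous measure across groups
#'
#' Equal-variance one-way analysis of variance (the classical F test).
#'
#' @param values numeric vector.
#' @param group factor of group labels, at least two groups with n >= 2.
#' @return list `statistic` (F), `df` (numerator, denominator), `p_value`.
#' @export
anova_continuous <- function(values, group) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]
  group <- droplevels(as.factor(group[keep]))
  if (nlevels(group) < 2 || any(table(group) < 2)) {
    stop("ANOVA requires at least two groups with n >= 2 each", call. = FALSE)
  }
  wvar <- tapply(values, group, stats::var)
  if (all(wvar == 0)) {
    stop("zero within-group variance in all groups", call. = FALSE)
  }
  ft <- stats::oneway.test(values ~ group, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       df = unname(c(ft$parameter[1], ft$parameter[2])),
       p_value = unname(ft$p.value))
}

#' Adjusted prevalence ratio from log-binomial regression
#'
#' Fits a binomial GLM with log link (prevalence-ratio scale) by IRLS and
#' returns the exponentiated exposure coefficient with its Wald 95% CI.
#' When the log-binomial fit fails to converge or produces fitted
#' probabilities at/above 1, the model is refit as a log-link Poisson
#' regression with a robust (HC0 sandwich) variance, flagged in `method`.
#' An exposure level with zero outcome events yields a non-converged
#' result rather than a degenerate estimate. Complete-case analysis: rows
#' with missing outcome, exposure or covariates are dropped with a
#' message.
#'
#' @param data data frame.
#' @param outcome name of a binary (logical/0-1) outcome column.
#' @param exposure name of the exposure column (first model term).
#' @param covariates character vector of adjustment covariate names.
#' @param conf_level confidence level for the Wald interval.
#' @return list of class `"cl_apr"`: `apr`, `ci_low`, `ci_high`,
#'   `p_value`, `converged`, `method` (`"log_binomial"` or
#'   `"poisson_robust_fallback"`), `n`, `n_dropped`, `message`.
#' @export
fit_prevalence_ratio <- function(data, outcome, exposure,
                                 covariates = character(0),
                                 conf_level = 0.95) {
  vars <- c(outcome, exposure, covariates)
  stopifnot(all(vars %in% names(data)))
  cc <- stats::complete.cases(data[vars])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message(sprintf("fit_prevalence_ratio: %d incomplete row(s) dropped", n_dropped))
  }
  dat <- data[cc, vars, drop = FALSE]
  y <- dat[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  dat[[outcome]] <- y

  fail <- function(msg) {
    structure(list(apr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   p_value = NA_real_, converged = FALSE, method = NA_character_,
                   n = nrow(dat), n_dropped = n_dropped, message = msg),
              class = "cl_apr")
  }
  ev <- table(dat[[exposure]], y)
  if (nrow(ev) < 2) return(fail("exposure has a single level"))
  if (ncol(ev) < 2 || any(ev[, "1"] == 0)) {
    return(fail("an exposure level has zero outcome events"))
  }

  f <- stats::reformulate(c(exposure, covariates), response = outcome)
  mm <- stats::model.matrix(f, dat)
  start <- c(log(max(mean(y), 1e-8)), rep(0, ncol(mm) - 1L))

  fit <- tryCatch(
    suppressWarnings(stats::glm(f, data = dat, family = stats::binomial("log"),
                                start = start,
                                control = stats::glm.control(maxit = 100,
                                                             epsilon = 1e-12))),
    error = function(e) NULL
  )
  method <- "log_binomial"
  if (is.null(fit) || !fit$converged || any(fit$fitted.values >= 1 - 1e-10)) {
    fit <- tryCatch(
      stats::glm(f, data = dat, family = stats::poisson("log")),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      return(fail("neither log-binomial nor Poisson fallback converged"))
    }
    method <- "poisson_robust_fallback"
    vc <- sandwich::vcovHC(fit, type = "HC0")
  } else {
    vc <- stats::vcov(fit)
  }

  # exposure is the first model term
  k <- which(attr(mm, "assign") == 1L)[1]
  b <- stats::coef(fit)[k]
  se <- sqrt(diag(vc))[k]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    apr = unname(exp(b)),
    ci_low = unname(exp(b - z * se)),
    ci_high = unname(exp(b + z * se)),
    p_value = unname(2 * stats::pnorm(-abs(b / se))),
    converged = TRUE, method = method,
    n = nrow(dat), n_dropped = n_dropped, message = NA_character_
  ), class = "cl_apr")
}

#' Fit the four adjusted clinical-outcome models
#'
#' The standard model suite contrasting cohort with non-cohort members:
#' Model 1 retention in any care in the outcome year; Model 2 ever
#' virally suppressed; Model 3 virally suppressed at the last lab of the
#' outcome year (persons without an outcome-year VL count as not
#' suppressed); Model 4, restricted to ever-suppressed persons with a
#' defined time-to-suppression, suppression after more than 24 months
#' versus within 24. All models adjust for gender identity, age at the
#' end of the outcome year, race/ethnicity, time since HIV diagnosis, and
#' mode of HIV transmission, entered via [fit_prevalence_ratio()].
#'
#' @param indicators per-person indicator table from
#'   [derive_indicators()].
#' @param persons persons data frame with demographics, `dob` and
#'   `hiv_diagnosis_date`.
#' @param group named factor (`"cohort"`/`"noncohort"`) over person ids,
#'   as returned by [partition_groups()].
#' @param window a [study_window()].
#' @return data frame with one row per model: `model`, `outcome`, `n`,
#'   `apr`, `ci_low`, `ci_high`, `p_value`, `method`, `converged`.
#' @export
run_model_suite <- function(indicators, persons, group, window = study_window()) {
  ref <- as.Date(sprintf("%d-12-31", window$outcome_year))
  dat <- merge(indicators, persons, by = "person_id")
  dat$in_cohort <- group[dat$person_id] == "cohort"
  dat$age_years <- years_between(dat$dob, ref)
  dat$years_since_dx <- years_between(dat$hiv_diagnosis_date, ref)
  dat$gender_identity <- factor(dat$gender_identity)
  dat$race_ethnicity <- factor(dat$race_ethnicity)
  dat$transmission_risk <- factor(dat$transmission_risk)
  covs <- c("gender_identity", "age_years", "race_ethnicity",
            "years_since_dx", "transmission_risk")

  dat$supp_last_2017 <- !is.na(dat$suppressed_last_lab_2017) &
    dat$suppressed_last_lab_2017
  dat$tts_gt24 <- dat$tts_category == ">24"

  specs <- list(
    list(model = "model1_retained_in_care", outcome = "care_2017", subset = TRUE),
    list(model = "model2_ever_suppressed", outcome = "ever_suppressed", subset = TRUE),
    list(model = "model3_suppressed_last_lab_2017", outcome = "supp_last_2017",
         subset = TRUE),
    list(model = "model4_tts_over_24m", outcome = "tts_gt24",
         subset = quote(ever_suppressed & !is.na(tts_category)))
  )
  rows <- lapply(specs, function(s) {
    sub <- if (isTRUE(s$subset)) dat else dat[eval(s$subset, dat), , drop = FALSE]
    est <- fit_prevalence_ratio(sub, s$outcome, "in_cohort", covs)
    data.frame(model = s$model, outcome = s$outcome, n = est$n,
               apr = est$apr, ci_low = est$ci_low, ci_high = est$ci_high,
               p_value = est$p_value,
               method = if (is.na(est$method)) NA_character_ else est$method,
               converged = est$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
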