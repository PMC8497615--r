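# Kaplan-Meier curves, the Mantel-Cox log-rank test, and stratified
# comparisons.

test_that("KM closed forms: all events, all censored", {
  km <- km_curve(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))

  cens <- km_curve(c(5, 7, 9), c(FALSE, FALSE, FALSE))
  expect_true(all(cens$surv == 1))
  expect_error(km_curve(numeric(0), logical(0)), "empty")
})

test_that("KM matches a hand-computed product-limit table on 8 subjects", {
  # times 1, 2+, 3, 4, 4+, 5, 6+, 7 (+ = censored); deaths precede
  # censorings at the tie at t = 4
  times <- c(1, 2, 3, 4, 4, 5, 6, 7)
  events <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  km <- km_curve(times, events)
  # hand: S(1)=7/8, S(3)=7/8*5/6, S(4)=...*4/5, S(5)=...*2/3, S(7)=0
  hand <- data.frame(time = c(1, 2, 3, 4, 5, 6, 7),
                     surv = c(7 / 8, 7 / 8, 7 / 8 * 5 / 6,
                              7 / 8 * 5 / 6 * 4 / 5,
                              7 / 8 * 5 / 6 * 4 / 5 * 2 / 3,
                              7 / 8 * 5 / 6 * 4 / 5 * 2 / 3,
                              0))
  expect_equal(km$time, hand$time)
  expect_equal(km$surv, hand$surv)
  expect_true(all(diff(km$surv) <= 1e-12))  # non-increasing
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(61)
  t <- sort(sample(1:50, 12))
  km <- km_curve(t, rep(TRUE, 12))
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$surv, emp)
})

test_that("log-rank is zero for identical groups and needs events", {
  g <- list(times = c(1, 2, 3, 4), events = c(TRUE, TRUE, FALSE, TRUE))
  res <- logrank(list(a = g, b = g))
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
  expect_equal(res$df, 1L)
  expect_error(logrank(list(a = g)), "at least 2")
  none <- list(times = c(1, 2), events = c(FALSE, FALSE))
  expect_error(logrank(list(a = none, b = none)), "no events")
})

test_that("log-rank matches the hand-computed O-E/V statistic", {
  # two-group toy with 4 events
  groups <- list(
    trt = list(times = c(2, 5, 8, 10), events = c(TRUE, TRUE, FALSE, FALSE)),
    ctl = list(times = c(1, 4, 6, 9), events = c(TRUE, FALSE, TRUE, FALSE)))
  res <- logrank(groups)
  manual <- manual_logrank(groups)
  expect_equal(res$chisq, manual$chisq, tolerance = 1e-10)
  expect_equal(res$table$observed, manual$O)
  expect_equal(res$table$expected, manual$E, tolerance = 1e-10)

  # and on a seeded 3-group example
  set.seed(67)
  g3 <- lapply(1:3, function(i) {
    list(times = round(rexp(15, 0.05), 1), events = runif(15) < 0.7)
  })
  names(g3) <- c("a", "b", "c")
  expect_equal(logrank(g3)$chisq, manual_logrank(g3)$chisq,
               tolerance = 1e-8)
})

test_that("log-rank is invariant to group order and time scaling", {
  set.seed(71)
  groups <- simulate_survival(80, hr = 2)
  r1 <- logrank(groups)
  r2 <- logrank(rev(groups))
  expect_equal(r1$chisq, r2$chisq)
  scaled <- lapply(groups, function(g) list(times = 3.7 * g$times,
                                            events = g$events))
  expect_equal(logrank(scaled)$chisq, r1$chisq)
  km1 <- km_curve(groups$carrier$times, groups$carrier$events)
  km2 <- km_curve(3.7 * groups$carrier$times, groups$carrier$events)
  expect_equal(km2$surv, km1$surv)
})

test_that("stratified comparison drops unmatched patients and odd strata", {
  clin <- data.frame(patient_id = sprintf("P%d", 1:10),
                     histology = "SCC",
                     os_months = c(5, 8, 12, 3, 20, 15, 7, 9, 30, 2),
                     os_event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                                  TRUE, FALSE, FALSE, TRUE),
                     covered_mb = NA_real_, stringsAsFactors = FALSE)
  strat <- stats::setNames(rep(c("mut", "wt"), each = 5),
                           c(sprintf("P%d", 1:5), sprintf("P%d", 6:9),
                             "MISSING"))
  res <- stratify_and_compare(clin, strat)
  expect_equal(res$n_missing_clinical, 1L)
  expect_equal(length(res$groups$mut$times), 5L)
  expect_equal(length(res$groups$wt$times), 4L)
  expect_true(res$test$p >= 0 && res$test$p <= 1)

  # a single stratum is a domain error
  expect_error(stratify_and_compare(clin, stats::setNames(
    rep("only", 10), clin$patient_id)), "fewer than 2")
})

test_that("DDR burden categories flow through to a survival comparison", {
  gen <- generate_cohort(cohort_config(n_patients = 80, seed = 73),
                         tempfile())
  b <- gen$truth$burden
  res <- stratify_and_compare(gen$clinical,
                              stats::setNames(b$mut_category, b$patient_id))
  # groups repartition the cohort exactly as a direct regrouping does
  for (cat in names(res$groups)) {
    ids <- b$patient_id[b$mut_category == cat]
    expect_setequal(res$groups[[cat]]$times,
                    gen$clinical$os_months[match(ids,
                                                 gen$clinical$patient_id)])
  }
  expect_equal(res$test$df, length(res$groups) - 1L)
})

test_that("written survival tables land on disk", {
  set.seed(79)
  groups <- simulate_survival(40, hr = 1.5)
  clin <- data.frame(
    patient_id = sprintf("S%02d", 1:40), histology = "SCC",
    os_months = c(groups$carrier$times, groups$noncarrier$times),
    os_event = c(groups$carrier$events, groups$noncarrier$events),
    covered_mb = NA_real_, stringsAsFactors = FALSE)
  strat <- stats::setNames(rep(c("carrier", "noncarrier"), each = 20),
                           clin$patient_id)
  cmp <- stratify_and_compare(clin, strat)
  dir <- tempfile()
  paths <- write_survival_tables(cmp, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "survival_km_carrier.tsv", "survival_km_noncarrier.tsv",
    "survival_logrank.tsv")))))
})
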