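test_that("the microsimulator is deterministic given its seed", {
  p <- calibrated_default_params()
  sched <- canonical_schedules()$scenario4
  a <- simulate_cohort(p, sched, n_persons_per_year = 4000, seed = 11,
                       n_replicates = 4, keep_persons = TRUE)
  b <- simulate_cohort(p, sched, n_persons_per_year = 4000, seed = 11,
                       n_replicates = 4, keep_persons = TRUE)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$summary, b$summary)
  expect_identical(a$persons, b$persons)
  c_ <- simulate_cohort(p, sched, n_persons_per_year = 4000, seed = 12,
                        n_replicates = 4)
  expect_false(identical(a$replicates, c_$replicates))
})

test_that("no screening and q = 0 produces zero detections in every replicate", {
  p <- set_symptomatic_fraction(default_parameters(), 0)
  sched <- uptake_schedule("nothing", rep(0, 3), rep(0, 3))
  ms <- simulate_cohort(p, sched, n_persons_per_year = 2000, seed = 5,
                        n_replicates = 6)
  for (oc in c("screen_detected_total", "symptom_detected", "total_cases",
               "early_stage_cases", "late_stage_cases")) {
    expect_true(all(ms$replicates[, oc] == 0))
  }
})

test_that("marginal FIT positivity matches the configured 7% rate", {
  p <- calibrated_default_params()
  sched <- canonical_schedules()$baseline
  ms <- simulate_cohort(p, sched, n_persons_per_year = 60000, seed = 21,
                        n_replicates = 1, keep_persons = TRUE)
  fit <- ms$persons[ms$persons$modality == "fit", ]
  n <- nrow(fit)
  phat <- mean(fit$fit_positive)
  se <- sqrt(0.07 * 0.93 / n)
  expect_lt(abs(phat - 0.07), 4 * se)
})

test_that("stage frequencies among FIT screen-detected cases converge to the FIT distribution", {
  p <- calibrated_default_params()
  sched <- uptake_schedule("fit_only", rep(0, 3), rep(1, 3))
  ms <- simulate_cohort(p, sched, n_persons_per_year = 120000, seed = 31,
                        n_replicates = 1, keep_persons = TRUE)
  det <- ms$persons[ms$persons$modality == "fit" &
                      ms$persons$detection == "screen", ]
  n <- nrow(det)
  expect_gt(n, 800)
  target <- c(I = 0.367, II = 0.347, III = 0.217, IV = 0.069)
  for (s in names(target)) {
    se <- sqrt(target[[s]] * (1 - target[[s]]) / n)
    expect_lt(abs(mean(det$stage == s) - target[[s]]), 4 * se)
  }
})

test_that("an inconsistent positivity/sensitivity/prevalence configuration is rejected", {
  p <- set_symptomatic_fraction(default_parameters(), 0.1)
  p$population$prevalence_crc <- 0.2
  p$tests$fit$sensitivity_crc <- 0.9
  p$tests$fit$positivity_rate <- 0.07  # implies a negative false-positive rate
  expect_error(simulate_cohort(p, canonical_schedules()$baseline,
                               n_persons_per_year = 100, seed = 1,
                               n_replicates = 1),
               "false-positive")
})

test_that("person-level export writes one row per person and re-exports identically", {
  p <- calibrated_default_params()
  sched <- canonical_schedules()$scenario3
  ms <- simulate_cohort(p, sched, n_persons_per_year = 500, seed = 3,
                        n_replicates = 2, keep_persons = TRUE)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  export_person_table(ms, f1)
  lines <- readLines(f1)
  expect_length(lines, 500 * 3 + 1)
  expect_identical(lines[1],
                   "\"year\",\"modality\",\"has_crc\",\"fit_positive\",\"completed_diagnostic\",\"detection\",\"stage\"")
  export_person_table(ms, f2)
  expect_identical(readLines(f2), lines)

  ms2 <- simulate_cohort(p, sched, n_persons_per_year = 500, seed = 3,
                         n_replicates = 1)
  expect_error(export_person_table(ms2, f1), "keep_persons")

  # record invariants: stage present iff detected; FIT fields only for FIT
  pp <- ms$persons
  expect_identical(is.na(pp$stage), pp$detection == "none")
  expect_true(all(is.na(pp$fit_positive[pp$modality != "fit"])))
  expect_true(all(!is.na(pp$fit_positive[pp$modality == "fit"])))
  expect_true(all(pp$has_crc[pp$detection == "screen"]))
  expect_true(all(pp$has_crc[pp$detection == "symptom"]))
})

test_that("replicate means track the deterministic engine (smoke, fixed seeds)", {
  p <- calibrated_default_params()
  for (sched in canonical_schedules()[c("baseline", "scenario4")]) {
    det <- run_cohort(p, sched)$totals
    ms <- simulate_cohort(p, sched, n_persons_per_year = 50000, seed = 17,
                          n_replicates = 10)
    sm <- ms$summary
    ok <- abs(sm$mean - det[sm$outcome]) <=
      4 * sm$se + 1e-6 * pmax(1, abs(det[sm$outcome]))
    expect_true(all(ok), info = paste("off:", paste(sm$outcome[!ok],
                                                    collapse = ", ")))
  }
})

test_that("Monte-Carlo standard errors shrink as replicates grow", {
  p <- calibrated_default_params()
  sched <- canonical_schedules()$scenario2
  few <- simulate_cohort(p, sched, n_persons_per_year = 20000, seed = 9,
                         n_replicates = 5)
  many <- simulate_cohort(p, sched, n_persons_per_year = 20000, seed = 9,
                          n_replicates = 40)
  i <- few$summary$outcome == "total_cases"
  expect_lt(many$summary$se[i], few$summary$se[i])
  expect_true(all(many$summary$se >= 0, na.rm = TRUE))
})
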