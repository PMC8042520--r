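test_that("a pure-FIT cohort yields sensitivity x adherence detections per screener", {
  # 100,000 FIT screeners x 0.8% prevalence x 0.79 sensitivity x 0.65
  # adherence = 410.8 screen-detected cases
  p <- default_parameters()
  p$population$annual_baseline_screeners <- 100000
  p$population$horizon_years <- 1L
  p <- set_symptomatic_fraction(p, 0)
  sched <- uptake_schedule("fit_only", colonoscopy = 0, fit = 1)
  out <- run_cohort(p, sched)
  expect_equal(unname(out$totals["screen_detected_fit"]), 410.8)
  expect_equal(unname(out$totals["screen_detected_colonoscopy"]), 0)
  # diagnostic-colonoscopy demand runs through positivity x adherence
  expect_equal(unname(out$totals["fit_diagnostic_colonoscopies"]),
               100000 * 0.07 * 0.65)
})

test_that("the baseline scenario screens 4,690,668 people over three years", {
  out <- run_cohort(calibrated_default_params(), canonical_schedules()$baseline)
  expect_equal(unname(out$totals["screened_total"]), 4690668)
  expect_equal(unname(out$totals["screened_colonoscopy"]), 4690668 * 0.85)
  expect_equal(unname(out$totals["unscreened"]), 0)
  expect_equal(unname(out$totals["symptom_detected"]), 576, tolerance = 1e-9)
})

test_that("symptomatic calibration is the closed-form target / pool ratio", {
  p <- default_parameters()
  base <- canonical_schedules()$baseline
  cal <- calibrate_symptomatic_fraction(p, 576, base)
  expect_equal(cal$q_undiagnosed, 576 / baseline_pool_by_hand(),
               tolerance = 1e-12)
  expect_identical(cal$source, "calibrated")

  # target 0 and linearity in the target
  expect_equal(calibrate_symptomatic_fraction(p, 0, base)$q_undiagnosed, 0)
  expect_equal(calibrate_symptomatic_fraction(p, 1152, base)$q_undiagnosed,
               2 * cal$q_undiagnosed, tolerance = 1e-12)

  # targets beyond the pool clamp with a warning
  expect_warning(
    clamped <- calibrate_symptomatic_fraction(p, 10 * baseline_pool_by_hand(),
                                              base),
    "clamped")
  expect_equal(clamped$q_undiagnosed, 1)
})

test_that("no screening and no symptomatic presentation means no detected cases", {
  p <- set_symptomatic_fraction(default_parameters(), 0)
  sched <- uptake_schedule("nothing", rep(0, 3), rep(0, 3))
  out <- run_cohort(p, sched)
  expect_equal(unname(out$totals["total_cases"]), 0)
  expect_equal(unname(out$totals["undiagnosed_remaining"]),
               unname(out$totals["prevalent_cases"]))
})

test_that("person and case accounting balances for randomized inputs", {
  set.seed(101)
  for (i in 1:60) {
    p <- random_params()
    sched <- random_schedule()
    out <- run_cohort(p, sched)
    t <- out$totals
    B <- p$population$annual_baseline_screeners
    # conservation of persons (unscreened recomputed as the remainder)
    expect_equal(unname(t["screened_total"] + t["unscreened"]), B * 3,
                 tolerance = 1e-9 * B)
    expect_equal(unname(t["screened_total"]),
                 unname(t["screened_colonoscopy"] + t["screened_fit"]))
    # case accounting: detected + remaining = all prevalent cancers
    expect_equal(unname(t["screen_detected_total"] + t["symptom_detected"] +
                          t["undiagnosed_remaining"]),
                 unname(t["prevalent_cases"]), tolerance = 1e-9 * B)
    expect_equal(unname(t["total_cases"]),
                 unname(t["screen_detected_total"] + t["symptom_detected"]))
    # stage counts partition the diagnosed cases
    expect_equal(unname(t["stage_I"] + t["stage_II"] + t["stage_III"] +
                          t["stage_IV"]),
                 unname(t["total_cases"]), tolerance = 1e-9 * max(1, t["total_cases"]))
    expect_equal(unname(t["early_stage_cases"] + t["late_stage_cases"]),
                 unname(t["total_cases"]), tolerance = 1e-9 * max(1, t["total_cases"]))
    expect_true(all(t[!is.na(t)] >= 0))
    # per-year rows balance too
    expect_equal(out$by_year$early_stage_cases + out$by_year$late_stage_cases,
                 out$by_year$total_cases, tolerance = 1e-9)
  }
})

test_that("shifting unscreened persons to FIT never loses cases; sensitivity gains never lose detections", {
  set.seed(202)
  for (i in 1:40) {
    p <- random_params()
    sched <- random_schedule()
    shifted <- apply_fit_expansion(sched, runif(1, 0.05, 0.9))
    a <- run_cohort(p, sched)$totals
    b <- run_cohort(p, shifted)$totals
    expect_gte(b[["total_cases"]], a[["total_cases"]] - 1e-9)
    expect_gte(b[["early_stage_cases"]], a[["early_stage_cases"]] - 1e-9)

    p2 <- p
    p2$tests$fit$sensitivity_crc <- min(1, p$tests$fit$sensitivity_crc + 0.1)
    p2$tests$colonoscopy$sensitivity_crc <-
      min(1, p$tests$colonoscopy$sensitivity_crc + 0.03)
    c_ <- run_cohort(p2, sched)$totals
    expect_gte(c_[["screen_detected_total"]], a[["screen_detected_total"]] - 1e-9)
  }
})

test_that("outcomes are homogeneous of degree one in the cohort size", {
  set.seed(303)
  for (i in 1:20) {
    p <- random_params()
    sched <- random_schedule()
    k <- runif(1, 0.1, 20)
    p2 <- p
    p2$population$annual_baseline_screeners <-
      p$population$annual_baseline_screeners * k
    a <- run_cohort(p, sched)$totals
    b <- run_cohort(p2, sched)$totals
    nz <- !is.na(a) & a != 0
    expect_true(all(abs(b[nz] / a[nz] - k) < 1e-12 * k))
    expect_true(all(b[!is.na(a) & a == 0] == 0))
  }
})

test_that("the overall early-stage fraction stays between the clinical and FIT screen-detected fractions", {
  set.seed(404)
  p <- default_parameters()  # default stage tables: clinical 0.52, FIT 0.714
  for (i in 1:40) {
    p$symptomatic <- list(q_undiagnosed = runif(1), source = "user_supplied")
    out <- run_cohort(p, random_schedule())$totals
    if (out[["total_cases"]] > 0) {
      frac <- out[["early_stage_cases"]] / out[["total_cases"]]
      expect_gte(frac, 0.52 - 1e-12)
      expect_lte(frac, 0.714 + 1e-12)
    }
  }
})

test_that("scenario comparison signs, self-comparison, and zero references behave", {
  runs <- run_all_published_scenarios()
  s1 <- runs$outcomes$scenario1
  base <- runs$outcomes$baseline

  self <- compare_scenarios(s1, s1)
  expect_true(all(self$absolute == 0))
  expect_true(all(self$percent[!is.na(self$percent)] == 0))

  d <- compare_scenarios(base, s1)
  i <- d$outcome == "screened_total"
  expect_lt(d$absolute[i], 0)  # scenario 1 screens fewer people
  expect_equal(d$percent[i], 100 * d$absolute[i] / d$reference[i])
  # baseline has zero unscreened: percent difference is undefined, not Inf
  expect_true(is.na(d$percent[d$outcome == "unscreened"]))
  expect_false(any(is.infinite(d$percent), na.rm = TRUE))
})

test_that("published-scenario runs share one baseline-calibrated q and order as published", {
  runs <- run_all_published_scenarios()
  qs <- vapply(runs$outcomes, function(o) o$q_undiagnosed, numeric(1))
  expect_true(all(qs == qs[["baseline"]]))
  tot <- vapply(runs$outcomes, function(o) o$totals[["screened_total"]],
                numeric(1))
  # scenario 2 (prolonged disruption) screens fewer than scenario 1, and FIT
  # expansion recovers volume: 3 > 1, 4 > 2
  expect_lt(tot[["scenario2"]], tot[["scenario1"]])
  expect_gt(tot[["scenario3"]], tot[["scenario1"]])
  expect_gt(tot[["scenario4"]], tot[["scenario2"]])
  # FIT screen-detected cases carry the FIT early fraction exactly
  fit_stages <- runs$params$stages$screen_fit
  expect_equal(unname(fit_stages[["I"]] + fit_stages[["II"]]), 0.714)
})

test_that("engine rejects mismatched horizons and an unset q", {
  p <- default_parameters()
  expect_error(run_cohort(set_symptomatic_fraction(p, 0.1),
                          uptake_schedule("short", 0.8, 0.2)),
               "horizon")
  expect_error(run_cohort(p, canonical_schedules()$baseline), "q_undiagnosed")
})
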