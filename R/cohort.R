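# Deterministic cohort engine: schedules + parameters -> screened counts,
# cases by detection route, stage at diagnosis; scenario comparison.

OUTCOME_NAMES <- c(
  "screened_colonoscopy", "screened_fit", "screened_total", "unscreened",
  "prevalent_cases", "screen_detected_colonoscopy", "screen_detected_fit",
  "screen_detected_total", "symptom_detected", "total_cases",
  "undiagnosed_remaining", "fit_diagnostic_colonoscopies",
  "stage_I", "stage_II", "stage_III", "stage_IV",
  "early_stage_cases", "late_stage_cases"
)

# effective unscreened remainder: published rows are rounded to whole percent,
# so persons are conserved by recomputing the remainder from colo + FIT;
# remainders below numeric noise are snapped to an exact zero
effective_unscreened <- function(schedule) {
  r <- 1 - schedule$p_colonoscopy - schedule$p_fit
  r[abs(r) < 1e-9] <- 0
  pmax(0, r)
}

#' Run the deterministic cohort model
#'
#' For each model year, the annual would-be-screened cohort (everyone who
#' would have screened in a normal year) is split by the schedule into
#' colonoscopy, FIT and unscreened arms. Prevalent cancers are detected by
#' screening with probability `sensitivity` for colonoscopy and
#' `sensitivity x diagnostic_adherence` for FIT (a positive FIT yields a
#' diagnosis only after a completed follow-up colonoscopy). Cancers left
#' undiagnosed by screening — false negatives, FIT-positive non-adherers,
#' and all prevalent cancers among the unscreened — present clinically with
#' probability `q_undiagnosed`. Screen-detected cases receive the
#' modality-specific stage-at-diagnosis distribution; symptom-detected cases
#' the (more advanced) clinical distribution. Annual cohorts are disjoint:
#' nobody is screened twice and undiagnosed persons do not carry over.
#'
#' Counts are kept as real numbers; rounding to whole persons happens only in
#' rendered tables.
#'
#' @param params A `crc_params` object with `symptomatic$q_undiagnosed` set
#'   (see [calibrate_symptomatic_fraction()]).
#' @param schedule An `uptake_schedule` spanning `population$horizon_years`.
#' @return A `crc_outcomes` object: list with `scenario_id`, `by_year` (data
#'   frame, one row per year) and `totals` (named vector over the horizon).
#' @examples
#' params <- default_parameters()
#' sched <- canonical_schedules()$baseline
#' params <- set_symptomatic_fraction(params,
#'   calibrate_symptomatic_fraction(params, 576, sched))
#' run_cohort(params, sched)
#' @export
run_cohort <- function(params, schedule) {
  validate_parameters(params)
  pop <- params$population
  if (nrow(schedule) != pop$horizon_years) {
    stop(sprintf("schedule spans %d years but the population horizon is %d",
                 nrow(schedule), pop$horizon_years), call. = FALSE)
  }
  q <- params$symptomatic$q_undiagnosed
  if (is.na(q)) {
    stop("symptomatic$q_undiagnosed is unset; calibrate it with ",
         "calibrate_symptomatic_fraction() or supply a value", call. = FALSE)
  }
  B <- pop$annual_baseline_screeners
  prev <- pop$prevalence_crc
  sens_c <- params$tests$colonoscopy$sensitivity_crc
  sens_f <- params$tests$fit$sensitivity_crc
  adh <- params$tests$fit$diagnostic_adherence
  pos <- params$tests$fit$positivity_rate
  eff_f <- sens_f * adh

  pc <- schedule$p_colonoscopy
  pf <- schedule$p_fit
  pu <- effective_unscreened(schedule)

  screened_colo <- B * pc
  screened_fit <- B * pf
  unscreened <- B * pu

  cases_colo <- screened_colo * prev
  cases_fit <- screened_fit * prev
  cases_unscr <- unscreened * prev
  prevalent <- cases_colo + cases_fit + cases_unscr

  det_colo <- cases_colo * sens_c
  det_fit <- cases_fit * eff_f
  pool <- cases_colo * (1 - sens_c) + cases_fit * (1 - eff_f) + cases_unscr
  symptom <- q * pool
  remaining <- (1 - q) * pool
  total_cases <- det_colo + det_fit + symptom

  if (any(c(screened_colo, screened_fit, unscreened, det_colo, det_fit,
            symptom, remaining) < -1e-9)) {
    stop("negative intermediate count: invalid inputs", call. = FALSE)
  }

  st <- params$stages
  stage <- sapply(STAGE_NAMES, function(s) {
    det_colo * st$screen_colonoscopy[[s]] + det_fit * st$screen_fit[[s]] +
      symptom * st$clinical[[s]]
  })
  if (is.null(dim(stage))) stage <- matrix(stage, nrow = 1,
                                           dimnames = list(NULL, STAGE_NAMES))
  early <- stage[, "I"] + stage[, "II"]
  late <- stage[, "III"] + stage[, "IV"]

  # diagnostic-colonoscopy demand generated by positive FITs (reporting only;
  # the detection pathway runs through sensitivity x adherence)
  fit_diag <- if (is.na(pos)) rep(NA_real_, length(pf)) else
    screened_fit * pos * adh

  by_year <- data.frame(
    year = schedule$year,
    screened_colonoscopy = screened_colo,
    screened_fit = screened_fit,
    screened_total = screened_colo + screened_fit,
    unscreened = unscreened,
    prevalent_cases = prevalent,
    screen_detected_colonoscopy = det_colo,
    screen_detected_fit = det_fit,
    screen_detected_total = det_colo + det_fit,
    symptom_detected = symptom,
    total_cases = total_cases,
    undiagnosed_remaining = remaining,
    fit_diagnostic_colonoscopies = fit_diag,
    stage_I = stage[, "I"],
    stage_II = stage[, "II"],
    stage_III = stage[, "III"],
    stage_IV = stage[, "IV"],
    early_stage_cases = early,
    late_stage_cases = late
  )
  totals <- colSums(by_year[, OUTCOME_NAMES, drop = FALSE])
  out <- list(
    scenario_id = attr(schedule, "scenario_id"),
    by_year = by_year,
    totals = totals,
    q_undiagnosed = q,
    horizon_years = nrow(schedule)
  )
  class(out) <- "crc_outcomes"
  out
}

#' Calibrate the symptomatic-presentation fraction
#'
#' The symptomatic pathway is linear in `q_undiagnosed`, so calibration to a
#' target count of symptom-detected cases is closed-form: `q` is the target
#' divided by the undiagnosed-cancer pool implied by the schedule (false
#' negatives, FIT-positive non-adherers and unscreened prevalent cancers).
#' The result is clamped to \eqn{[0,1]} with a warning if the target exceeds
#' the pool.
#'
#' @param params A `crc_params` object (its current `q` is ignored).
#' @param target_symptom_detected Target count of symptom-detected cases over
#'   the horizon; the published baseline value is 576.
#' @param schedule The `uptake_schedule` under which the target was observed.
#' @return A list `(q_undiagnosed, source = "calibrated")` suitable for
#'   [set_symptomatic_fraction()].
#' @export
calibrate_symptomatic_fraction <- function(params, target_symptom_detected,
                                           schedule) {
  if (target_symptom_detected < 0) stop("target must be >= 0", call. = FALSE)
  p0 <- params
  p0$symptomatic <- list(q_undiagnosed = 0, source = "user_supplied")
  pool <- unname(run_cohort(p0, schedule)$totals["undiagnosed_remaining"])
  if (pool <= 0) {
    if (target_symptom_detected > 0) {
      stop("undiagnosed pool is empty; cannot calibrate to a nonzero target",
           call. = FALSE)
    }
    return(list(q_undiagnosed = 0, source = "calibrated"))
  }
  q <- target_symptom_detected / pool
  if (q > 1) {
    warning(sprintf("calibrated q = %.4f exceeds 1; clamped", q))
    q <- 1
  }
  list(q_undiagnosed = q, source = "calibrated")
}

#' Compare two scenario outcomes
#'
#' Absolute differences are comparator minus reference (negative = the
#' comparator falls below the reference); percent differences are relative to
#' the reference and reported as `NA` where the reference outcome is zero.
#' Differences are computed on unrounded counts.
#'
#' @param reference,comparator `crc_outcomes` objects over the same horizon.
#' @return A `crc_comparison`: data frame with columns `outcome`,
#'   `reference`, `comparator`, `absolute`, `percent`.
#' @export
compare_scenarios <- function(reference, comparator) {
  if (reference$horizon_years != comparator$horizon_years) {
    stop("scenarios span different horizons", call. = FALSE)
  }
  ref <- reference$totals
  cmp <- comparator$totals
  absolute <- cmp - ref
  percent <- ifelse(is.na(ref) | ref == 0, NA_real_, 100 * absolute / ref)
  out <- data.frame(
    outcome = names(ref),
    reference = unname(ref),
    comparator = unname(cmp),
    absolute = unname(absolute),
    percent = unname(percent)
  )
  attr(out, "reference_id") <- reference$scenario_id
  attr(out, "comparator_id") <- comparator$scenario_id
  class(out) <- c("crc_comparison", "data.frame")
  out
}

#' Run the five published scenarios and their comparisons
#'
#' Runs the baseline and the four pandemic scenarios from
#' [canonical_schedules()]. The symptomatic fraction `q` is calibrated once
#' on the baseline scenario (default target: the published 576
#' symptom-detected cases) and reused for every scenario. The published
#' comparisons are computed: each scenario against baseline, scenario 3
#' against 1, and scenario 4 against 2.
#'
#' @param params A `crc_params` object; its `q` is replaced by the baseline
#'   calibration unless `symptomatic$source == "user_supplied"`.
#' @param symptom_target Baseline symptom-detected count to calibrate to.
#' @return A `crc_run_set`: list with `outcomes` (five `crc_outcomes`),
#'   `comparisons` (six `crc_comparison`s), `params` (as used, with the
#'   calibrated `q`).
#' @export
run_all_published_scenarios <- function(params = default_parameters(),
                                        symptom_target = 576) {
  schedules <- canonical_schedules()
  if (!identical(params$symptomatic$source, "user_supplied") ||
      is.na(params$symptomatic$q_undiagnosed)) {
    params <- set_symptomatic_fraction(
      params,
      calibrate_symptomatic_fraction(params, symptom_target, schedules$baseline))
  }
  outcomes <- lapply(schedules, function(s) run_cohort(params, s))
  comparisons <- list(
    scenario1_vs_baseline = compare_scenarios(outcomes$baseline, outcomes$scenario1),
    scenario2_vs_baseline = compare_scenarios(outcomes$baseline, outcomes$scenario2),
    scenario3_vs_baseline = compare_scenarios(outcomes$baseline, outcomes$scenario3),
    scenario4_vs_baseline = compare_scenarios(outcomes$baseline, outcomes$scenario4),
    scenario3_vs_scenario1 = compare_scenarios(outcomes$scenario1, outcomes$scenario3),
    scenario4_vs_scenario2 = compare_scenarios(outcomes$scenario2, outcomes$scenario4)
  )
  out <- list(outcomes = outcomes, comparisons = comparisons, params = params)
  class(out) <- "crc_run_set"
  out
}

# round half away from zero, as published tables do
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.crc_outcomes <- function(x, ...) {
  t <- x$totals
  cat(sprintf("CRC cohort outcomes, scenario '%s' (%d-year totals)\n",
              x$scenario_id, x$horizon_years))
  fmt <- function(v) format(round_half_up(v), big.mark = ",", scientific = FALSE)
  cat(sprintf("  people screened: %s (colonoscopy %s, FIT %s); unscreened %s\n",
              fmt(t[["screened_total"]]), fmt(t[["screened_colonoscopy"]]),
              fmt(t[["screened_fit"]]), fmt(t[["unscreened"]])))
  cat(sprintf("  CRC cases: %s (screen-detected %s [%.1f%%], symptom-detected %s [%.1f%%])\n",
              fmt(t[["total_cases"]]), fmt(t[["screen_detected_total"]]),
              100 * t[["screen_detected_total"]] / t[["total_cases"]],
              fmt(t[["symptom_detected"]]),
              100 * t[["symptom_detected"]] / t[["total_cases"]]))
  cat(sprintf("  early stage (I-II): %s (%.1f%%); late stage (III-IV): %s (%.1f%%)\n",
              fmt(t[["early_stage_cases"]]),
              100 * t[["early_stage_cases"]] / t[["total_cases"]],
              fmt(t[["late_stage_cases"]]),
              100 * t[["late_stage_cases"]] / t[["total_cases"]]))
  cat(sprintf("  undiagnosed prevalent cancers remaining: %s (q = %.4f)\n",
              fmt(t[["undiagnosed_remaining"]]), x$q_undiagnosed))
  invisible(x)
}

#' @export
summary.crc_outcomes <- function(object, ...) {
  object$by_year
}

#' @export
as.data.frame.crc_outcomes <- function(x, ...) {
  long <- utils::stack(as.list(x$totals))
  data.frame(scenario = x$scenario_id, outcome = as.character(long$ind),
             year = "total", value = long$values)
}

#' @export
print.crc_comparison <- function(x, ...) {
  cat(sprintf("Scenario comparison: %s vs %s (comparator - reference)\n",
              attr(x, "comparator_id"), attr(x, "reference_id")))
  key <- x$outcome %in% c("screened_total", "total_cases",
                          "screen_detected_total", "symptom_detected",
                          "early_stage_cases", "late_stage_cases")
  df <- x[key, ]
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-24s %12s (%s)\n", df$outcome[i],
                format(round_half_up(df$absolute[i]), big.mark = ","),
                ifelse(is.na(df$percent[i]), "NA",
                       sprintf("%+.1f%%", df$percent[i]))))
  }
  invisible(x)
}

#' @export
print.crc_run_set <- function(x, ...) {
  cat("Published COVID-19 CRC screening scenarios\n")
  cat(sprintf("  symptomatic fraction q = %.4f (%s)\n\n",
              x$params$symptomatic$q_undiagnosed, x$params$symptomatic$source))
  wide <- sapply(x$outcomes, function(o) o$totals[c(
    "screened_total", "total_cases", "screen_detected_total",
    "symptom_detected", "early_stage_cases")])
  rownames(wide) <- c("People screened", "New CRC cases", "Screen-detected",
                      "Symptom-detected", "Early stage (I-II)")
  print(format(round_half_up(wide), big.mark = ",", scientific = FALSE),
        quote = FALSE)
  invisible(x)
}
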