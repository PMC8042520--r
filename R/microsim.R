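# Individual-level Monte-Carlo microsimulator with the exact statistical
# structure the deterministic cohort engine assumes. Serves as a brute-force
# oracle for the engine and as a generator of person-level synthetic data.

# FIT false-positive rate among cancer-free screeners, chosen so the marginal
# positivity across all FIT screeners equals the configured rate:
#   positivity = prevalence * sensitivity + (1 - prevalence) * fp_rate
fit_false_positive_rate <- function(params) {
  pos <- params$tests$fit$positivity_rate
  prev <- params$population$prevalence_crc
  sens <- params$tests$fit$sensitivity_crc
  fp <- (pos - prev * sens) / (1 - prev)
  if (is.na(fp) || fp < 0 || fp > 1) {
    stop(sprintf(
      "implied FIT false-positive rate %.4f outside [0, 1]: positivity, sensitivity and prevalence are inconsistent",
      fp), call. = FALSE)
  }
  fp
}

simulate_one_replicate <- function(params, schedule, n, keep_persons) {
  pop <- params$population
  prev <- pop$prevalence_crc
  sens_c <- params$tests$colonoscopy$sensitivity_crc
  sens_f <- params$tests$fit$sensitivity_crc
  adh <- params$tests$fit$diagnostic_adherence
  fp <- fit_false_positive_rate(params)
  q <- params$symptomatic$q_undiagnosed
  st <- params$stages

  pu <- effective_unscreened(schedule)
  counts <- stats::setNames(numeric(length(OUTCOME_NAMES)), OUTCOME_NAMES)
  persons <- if (keep_persons) vector("list", nrow(schedule)) else NULL

  for (y in seq_len(nrow(schedule))) {
    cuts <- cumsum(c(schedule$p_colonoscopy[y], schedule$p_fit[y], pu[y]))
    u <- stats::runif(n) * cuts[3]
    modality <- c("colonoscopy", "fit", "none")[findInterval(u, cuts) + 1L]
    has_crc <- stats::runif(n) < prev

    is_colo <- modality == "colonoscopy"
    is_fit <- modality == "fit"

    det_colo <- is_colo & has_crc & stats::runif(n) < sens_c

    fit_positive <- rep(NA, n)
    fit_positive[is_fit] <- stats::runif(sum(is_fit)) <
      ifelse(has_crc[is_fit], sens_f, fp)
    completed <- rep(NA, n)
    pos_idx <- which(is_fit & fit_positive)
    completed[is_fit] <- FALSE
    completed[pos_idx] <- stats::runif(length(pos_idx)) < adh
    det_fit <- is_fit & has_crc & !is.na(fit_positive) & fit_positive &
      !is.na(completed) & completed

    screen_detected <- det_colo | det_fit
    undiag <- has_crc & !screen_detected
    symptom <- undiag & stats::runif(n) < q

    stage <- rep(NA_character_, n)
    draw_stage <- function(idx, p) {
      if (length(idx)) sample(STAGE_NAMES, length(idx), replace = TRUE, prob = p)
      else character(0)
    }
    stage[det_colo] <- draw_stage(which(det_colo), st$screen_colonoscopy)
    stage[det_fit] <- draw_stage(which(det_fit), st$screen_fit)
    stage[symptom] <- draw_stage(which(symptom), st$clinical)

    counts["screened_colonoscopy"] <- counts["screened_colonoscopy"] + sum(is_colo)
    counts["screened_fit"] <- counts["screened_fit"] + sum(is_fit)
    counts["unscreened"] <- counts["unscreened"] + sum(modality == "none")
    counts["prevalent_cases"] <- counts["prevalent_cases"] + sum(has_crc)
    counts["screen_detected_colonoscopy"] <-
      counts["screen_detected_colonoscopy"] + sum(det_colo)
    counts["screen_detected_fit"] <- counts["screen_detected_fit"] + sum(det_fit)
    counts["symptom_detected"] <- counts["symptom_detected"] + sum(symptom)
    counts["undiagnosed_remaining"] <-
      counts["undiagnosed_remaining"] + sum(undiag & !symptom)
    counts["fit_diagnostic_colonoscopies"] <-
      counts["fit_diagnostic_colonoscopies"] +
      sum(completed[pos_idx], na.rm = TRUE)
    for (s in STAGE_NAMES) {
      counts[paste0("stage_", s)] <- counts[paste0("stage_", s)] +
        sum(stage == s, na.rm = TRUE)
    }

    if (keep_persons) {
      detection <- ifelse(screen_detected, "screen",
                          ifelse(symptom, "symptom", "none"))
      persons[[y]] <- data.frame(
        year = y, modality = modality, has_crc = has_crc,
        fit_positive = fit_positive, completed_diagnostic = completed,
        detection = detection, stage = stage
      )
    }
  }
  counts["screened_total"] <- counts["screened_colonoscopy"] + counts["screened_fit"]
  counts["screen_detected_total"] <-
    counts["screen_detected_colonoscopy"] + counts["screen_detected_fit"]
  counts["total_cases"] <- counts["screen_detected_total"] + counts["symptom_detected"]
  counts["early_stage_cases"] <- counts["stage_I"] + counts["stage_II"]
  counts["late_stage_cases"] <- counts["stage_III"] + counts["stage_IV"]
  list(counts = counts,
       persons = if (keep_persons) do.call(rbind, persons) else NULL)
}

#' Monte-Carlo microsimulation of the screening cohort
#'
#' Simulates `n_persons_per_year` individuals per model year, each drawing a
#' screening modality from the schedule, cancer status from prevalence, test
#' results from the modality's characteristics (FIT positivity among
#' cancer-free screeners is derived so the marginal positivity matches the
#' configured rate), diagnostic completion from adherence, symptomatic
#' presentation from `q_undiagnosed`, and a stage from the detection route's
#' distribution. Counts are scaled by `annual_baseline_screeners /
#' n_persons_per_year` to cohort scale, so replicate means are directly
#' comparable with [run_cohort()] totals.
#'
#' Each replicate runs on its own seed (`seed + replicate - 1`), so any
#' replicate can be reproduced individually and the whole result is
#' deterministic given `(seed, n_persons_per_year, n_replicates)`.
#'
#' @param params A `crc_params` object with `q_undiagnosed` set.
#' @param schedule An `uptake_schedule`.
#' @param n_persons_per_year Simulated persons per model year.
#' @param seed Integer seed for the first replicate.
#' @param n_replicates Number of independent replicates.
#' @param keep_persons If `TRUE`, retain the person-level table of the first
#'   replicate (unscaled) for [export_person_table()].
#' @return A `crc_microsim` object: list with `summary` (data frame of
#'   per-outcome replicate mean and Monte-Carlo standard error on cohort
#'   scale), `replicates` (outcome matrix), `persons` (data frame or `NULL`),
#'   and the run settings.
#' @examples
#' params <- set_symptomatic_fraction(default_parameters(), 0.13)
#' simulate_cohort(params, canonical_schedules()$baseline,
#'                 n_persons_per_year = 5000, seed = 1, n_replicates = 5)
#' @export
simulate_cohort <- function(params, schedule, n_persons_per_year = 200000,
                            seed = 1, n_replicates = 50,
                            keep_persons = FALSE) {
  validate_parameters(params)
  if (n_persons_per_year < 1 || n_replicates < 1) {
    stop("n_persons_per_year and n_replicates must be >= 1", call. = FALSE)
  }
  if (is.na(params$symptomatic$q_undiagnosed)) {
    stop("symptomatic$q_undiagnosed is unset", call. = FALSE)
  }
  fit_false_positive_rate(params)  # fail fast on inconsistent configuration

  scale <- params$population$annual_baseline_screeners / n_persons_per_year
  reps <- matrix(NA_real_, nrow = n_replicates, ncol = length(OUTCOME_NAMES),
                 dimnames = list(NULL, OUTCOME_NAMES))
  persons <- NULL
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r - 1L)
    one <- simulate_one_replicate(params, schedule, n_persons_per_year,
                                  keep_persons = keep_persons && r == 1L)
    reps[r, ] <- one$counts[OUTCOME_NAMES] * scale
    if (r == 1L) persons <- one$persons
  }
  se <- apply(reps, 2, stats::sd) / sqrt(n_replicates)
  if (n_replicates == 1L) se[] <- NA_real_
  out <- list(
    scenario_id = attr(schedule, "scenario_id"),
    seed = seed, n_persons_per_year = n_persons_per_year,
    n_replicates = n_replicates, scale = scale,
    summary = data.frame(outcome = OUTCOME_NAMES,
                         mean = unname(colMeans(reps)), se = unname(se)),
    replicates = reps,
    persons = persons
  )
  class(out) <- "crc_microsim"
  out
}

#' Export the retained person-level table as CSV
#'
#' One row per simulated person of the first replicate (unscaled). Columns:
#' `year` (model year), `modality` (`colonoscopy`/`fit`/`none`), `has_crc`,
#' `fit_positive` and `completed_diagnostic` (`NA` unless modality is
#' `fit`; completion `NA` for non-positives is written as `FALSE` only when
#' a positive occurred), `detection` (`screen`/`symptom`/`none`), `stage`
#' (`I`–`IV`, empty unless detected). Re-export is byte-identical.
#'
#' @param result A `crc_microsim` run with `keep_persons = TRUE`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
export_person_table <- function(result, path) {
  if (is.null(result$persons)) {
    stop("person-level table was not retained; rerun simulate_cohort() with ",
         "keep_persons = TRUE", call. = FALSE)
  }
  utils::write.csv(result$persons, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.crc_microsim <- function(x, ...) {
  cat(sprintf(
    "Microsimulation, scenario '%s': %s persons/year x %d replicates (seed %d)\n",
    x$scenario_id, format(x$n_persons_per_year, big.mark = ","),
    x$n_replicates, x$seed))
  key <- x$summary$outcome %in% c("screened_total", "total_cases",
                                  "screen_detected_total", "symptom_detected",
                                  "early_stage_cases")
  df <- x$summary[key, ]
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-24s mean %14.1f   MC se %10.1f\n",
                df$outcome[i], df$mean[i], df$se[i]))
  }
  invisible(x)
}
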