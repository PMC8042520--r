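# Per-year modality uptake schedules and their construction from a monthly
# pandemic dispersion profile and a FIT-expansion rule.

#' Construct a per-year modality uptake schedule
#'
#' A schedule gives, for each model year, the fractions of the annual
#' would-be-screened cohort completing colonoscopy, completing FIT, or
#' remaining unscreened. Published rows are stored exactly as printed; whole
#' -percent rounding means a yearly row may sum to anything in
#' \eqn{[0.99, 1.01]} (the cohort engine recomputes the unscreened remainder
#' as \eqn{1 - p_{colo} - p_{fit}} so that persons are conserved).
#'
#' @param scenario_id Label for the scenario.
#' @param colonoscopy,fit Numeric vectors, one value per year, proportions.
#' @param not_screened Optional; defaults to `1 - colonoscopy - fit`.
#' @return An `uptake_schedule`: a data frame with columns `year`,
#'   `p_colonoscopy`, `p_fit`, `p_unscreened` and a `scenario_id` attribute.
#' @export
uptake_schedule <- function(scenario_id, colonoscopy, fit, not_screened = NULL) {
  n <- length(colonoscopy)
  if (length(fit) != n) {
    stop("colonoscopy and fit must have one value per year", call. = FALSE)
  }
  if (is.null(not_screened)) not_screened <- 1 - colonoscopy - fit
  if (length(not_screened) != n) {
    stop("not_screened must have one value per year", call. = FALSE)
  }
  all_p <- c(colonoscopy, fit, not_screened)
  if (any(all_p < -1e-9 | all_p > 1 + 1e-9)) {
    stop(sprintf("schedule '%s': every proportion must lie in [0, 1]", scenario_id),
         call. = FALSE)
  }
  sums <- colonoscopy + fit + not_screened
  if (any(sums < 0.99 - 1e-9 | sums > 1.01 + 1e-9)) {
    stop(sprintf("schedule '%s': yearly sums %s outside [0.99, 1.01]",
                 scenario_id, paste(round(sums, 3), collapse = ", ")),
         call. = FALSE)
  }
  out <- data.frame(
    year = seq_len(n),
    p_colonoscopy = as.numeric(colonoscopy),
    p_fit = as.numeric(fit),
    p_unscreened = as.numeric(not_screened)
  )
  attr(out, "scenario_id") <- scenario_id
  class(out) <- c("uptake_schedule", "data.frame")
  out
}

#' The five published uptake schedules
#'
#' The baseline (85% colonoscopy / 15% FIT every year) and the four pandemic
#' scenarios, with per-year percentages exactly as published. Scenarios 1–2
#' reduce colonoscopy volume for 9 vs 18 months with FIT frozen at 8%;
#' scenarios 3–4 add expanded FIT outreach on top of the same colonoscopy
#' recovery paths. The published year-average row is not stored; recompute it
#' with [three_year_average()].
#'
#' @return Named list of five `uptake_schedule` objects: `baseline`,
#'   `scenario1` … `scenario4`.
#' @examples
#' canonical_schedules()$scenario1
#' @export
canonical_schedules <- function() {
  list(
    baseline  = uptake_schedule("baseline",
                                colonoscopy = c(0.85, 0.85, 0.85),
                                fit = c(0.15, 0.15, 0.15),
                                not_screened = c(0, 0, 0)),
    scenario1 = uptake_schedule("scenario1",
                                colonoscopy = c(0.42, 0.58, 0.64),
                                fit = c(0.08, 0.08, 0.08),
                                not_screened = c(0.50, 0.34, 0.29)),
    scenario2 = uptake_schedule("scenario2",
                                colonoscopy = c(0.42, 0.42, 0.64),
                                fit = c(0.08, 0.08, 0.08),
                                not_screened = c(0.50, 0.50, 0.29)),
    scenario3 = uptake_schedule("scenario3",
                                colonoscopy = c(0.42, 0.58, 0.64),
                                fit = c(0.17, 0.22, 0.21),
                                not_screened = c(0.40, 0.19, 0.15)),
    scenario4 = uptake_schedule("scenario4",
                                colonoscopy = c(0.42, 0.42, 0.64),
                                fit = c(0.17, 0.27, 0.21),
                                not_screened = c(0.40, 0.31, 0.15))
  )
}

#' Construct a pandemic dispersion profile
#'
#' A dispersion profile is an ordered sequence of segments, each a number of
#' months during which screening runs at some fraction of pre-pandemic
#' volume. The published profiles use multipliers 1.0 (normal), 0 (full
#' suspension), 0.5 and 0.75.
#'
#' @param duration_months Positive integer vector of segment lengths.
#' @param volume_multiplier Same-length vector of multipliers in \eqn{[0,1]}.
#' @param horizon_months Total months the profile must span (default 36).
#' @return A `dispersion_profile` data frame.
#' @examples
#' # 3 normal months, 3 suspended, 9 at half volume, 21 at three-quarters
#' dispersion_profile(c(3, 3, 9, 21), c(1, 0, 0.5, 0.75))
#' @export
dispersion_profile <- function(duration_months, volume_multiplier,
                               horizon_months = 36L) {
  if (length(duration_months) != length(volume_multiplier)) {
    stop("duration_months and volume_multiplier must have equal length",
         call. = FALSE)
  }
  if (any(duration_months <= 0) || any(duration_months != round(duration_months))) {
    stop("segment durations must be positive integers", call. = FALSE)
  }
  if (any(volume_multiplier < 0 | volume_multiplier > 1)) {
    stop("volume multipliers must lie in [0, 1]", call. = FALSE)
  }
  if (sum(duration_months) != horizon_months) {
    stop(sprintf("profile spans %d months, expected %d",
                 sum(duration_months), horizon_months), call. = FALSE)
  }
  out <- data.frame(duration_months = as.integer(duration_months),
                    volume_multiplier = as.numeric(volume_multiplier))
  class(out) <- c("dispersion_profile", "data.frame")
  out
}

#' Derive a yearly uptake schedule from a monthly dispersion profile
#'
#' Each calendar year's uptake for a modality is the duration-weighted mean,
#' over that year's months, of the baseline modality share times the
#' segment's volume multiplier. Years are months 1–12, 13–24, 25–36; segments
#' may straddle year boundaries and are split by month. If
#' `fit_multiplier_override` is supplied, FIT uses it in place of the segment
#' multiplier — this expresses scenarios in which FIT volume does not track
#' the colonoscopy disruption (for instance a flat 8% FIT uptake while
#' colonoscopy recovers).
#'
#' @param profile A [dispersion_profile()].
#' @param baseline_mix Named proportions `c(colonoscopy = , fit = )`.
#' @param fit_multiplier_override `NULL`, a scalar, or one multiplier per
#'   profile segment.
#' @param scenario_id Label for the resulting schedule.
#' @return An `uptake_schedule`.
#' @examples
#' prof <- dispersion_profile(c(3, 3, 9, 21), c(1, 0, 0.5, 0.75))
#' schedule_from_profile(prof)  # year-1 colonoscopy = 0.425
#' @export
schedule_from_profile <- function(profile,
                                  baseline_mix = c(colonoscopy = 0.85, fit = 0.15),
                                  fit_multiplier_override = NULL,
                                  scenario_id = "custom") {
  months <- rep(profile$volume_multiplier, profile$duration_months)
  n_years <- length(months) %/% 12L
  if (length(months) != n_years * 12L) {
    stop("profile must span a whole number of years", call. = FALSE)
  }
  fit_months <- if (is.null(fit_multiplier_override)) {
    months
  } else {
    if (length(fit_multiplier_override) == 1L) {
      rep(fit_multiplier_override, length(months))
    } else if (length(fit_multiplier_override) == nrow(profile)) {
      rep(fit_multiplier_override, profile$duration_months)
    } else {
      stop("fit_multiplier_override must be scalar or one value per segment",
           call. = FALSE)
    }
  }
  year_of <- rep(seq_len(n_years), each = 12L)
  p_colo <- as.numeric(tapply(baseline_mix[["colonoscopy"]] * months, year_of, mean))
  p_fit <- as.numeric(tapply(baseline_mix[["fit"]] * fit_months, year_of, mean))
  uptake_schedule(scenario_id, p_colo, p_fit)
}

#' Expand FIT uptake into the unscreened pool
#'
#' Models a deliberate FIT-outreach response: each year, a fixed completion
#' rate (default 22.5%, the median organised-outreach FIT completion in a
#' large integrated health system) is applied to the pool of people who would
#' otherwise go unscreened, moving them from `p_unscreened` to `p_fit`.
#' Colonoscopy uptake and the yearly total are unchanged.
#'
#' @param schedule An `uptake_schedule`.
#' @param rate FIT completion rate applied to the unscreened pool.
#' @return The expanded `uptake_schedule`.
#' @export
apply_fit_expansion <- function(schedule, rate = 0.225) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1) {
    stop("rate must be a single proportion in [0, 1]", call. = FALSE)
  }
  moved <- rate * schedule$p_unscreened
  uptake_schedule(attr(schedule, "scenario_id"),
                  colonoscopy = schedule$p_colonoscopy,
                  fit = schedule$p_fit + moved,
                  not_screened = schedule$p_unscreened - moved)
}

#' Unweighted three-year average modality mix of a schedule
#'
#' @param schedule An `uptake_schedule`.
#' @return Named numeric triple `(colonoscopy, fit, not_screened)`.
#' @export
three_year_average <- function(schedule) {
  c(colonoscopy = mean(schedule$p_colonoscopy),
    fit = mean(schedule$p_fit),
    not_screened = mean(schedule$p_unscreened))
}

#' Save a schedule as CSV or YAML
#'
#' @param schedule An `uptake_schedule`.
#' @param path Destination; `.yaml`/`.yml` writes YAML, anything else CSV
#'   (rows = years, columns = modality proportions).
#' @return `path`, invisibly.
#' @export
save_schedule <- function(schedule, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(list(
      scenario_id = attr(schedule, "scenario_id"),
      years = lapply(seq_len(nrow(schedule)), function(i) list(
        year = schedule$year[i],
        colonoscopy = schedule$p_colonoscopy[i],
        fit = schedule$p_fit[i],
        not_screened = schedule$p_unscreened[i]
      ))
    ), path, precision = 15)
  } else {
    df <- as.data.frame(schedule)
    df$scenario_id <- attr(schedule, "scenario_id")
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.uptake_schedule <- function(x, ...) {
  cat(sprintf("Uptake schedule '%s'\n", attr(x, "scenario_id")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  year %d: colonoscopy %4.1f%%  FIT %4.1f%%  not screened %4.1f%%\n",
                x$year[i], 100 * x$p_colonoscopy[i], 100 * x$p_fit[i],
                100 * x$p_unscreened[i]))
  }
  avg <- three_year_average(x)
  cat(sprintf("  average: colonoscopy %4.1f%%  FIT %4.1f%%  not screened %4.1f%%\n",
              100 * avg[["colonoscopy"]], 100 * avg[["fit"]],
              100 * avg[["not_screened"]]))
  invisible(x)
}
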