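# Model parameters: construction, validation, file I/O.

STAGE_NAMES <- c("I", "II", "III", "IV")
STAGE_ROUTES <- c("screen_colonoscopy", "screen_fit", "clinical")

#' Base-case model parameters
#'
#' Returns the published base-case inputs of the screening model: test
#' characteristics (colonoscopy sensitivity 95%, FIT sensitivity 79%, FIT
#' positivity 7%, diagnostic-colonoscopy adherence after a positive FIT 65%),
#' CRC prevalence among the screening-eligible cohort (0.8%), the annual
#' would-be-screened population (1,563,556 persons/year for 3 years, 85%
#' colonoscopy / 15% FIT at baseline), stage-at-diagnosis distributions for
#' the three detection routes, and 95% CI ranges for every parameter carrying
#' one (parameters published without a CI get a degenerate range so the
#' sensitivity module can treat all parameters uniformly).
#'
#' The symptomatic-presentation fraction `q_undiagnosed` — the proportion of
#' prevalent cancers left undiagnosed by the screening process (false
#' negatives, FIT-positive non-adherers, and the unscreened) that present
#' clinically within the horizon — is not published; it defaults to `NA` with
#' `source = "calibrated"` and is normally set by
#' [calibrate_symptomatic_fraction()].
#'
#' @param prevalence_low_reading If `TRUE`, use the 0.08% prevalence reading
#'   (with CI 0.07–0.09%) instead of the 0.8% base case. The two readings both
#'   circulate for this model; 0.8% is the default because it is the only one
#'   consistent with the published case counts.
#' @return A `crc_params` object (validated list).
#' @examples
#' p <- default_parameters()
#' p$tests$fit$sensitivity_crc    # 0.79
#' @export
default_parameters <- function(prevalence_low_reading = FALSE) {
  prev <- if (prevalence_low_reading) c(0.0007, 0.0008, 0.0009) else
    c(0.007, 0.008, 0.009)
  params <- list(
    tests = list(
      colonoscopy = list(
        modality = "colonoscopy",
        sensitivity_crc = 0.95,
        positivity_rate = NA_real_,
        diagnostic_adherence = 1.0
      ),
      fit = list(
        modality = "fit",
        sensitivity_crc = 0.79,
        positivity_rate = 0.07,
        diagnostic_adherence = 0.65
      )
    ),
    stages = list(
      screen_colonoscopy = c(I = 0.34, II = 0.36, III = 0.19, IV = 0.11),
      screen_fit = c(I = 0.367, II = 0.347, III = 0.217, IV = 0.069),
      clinical = c(I = 0.18, II = 0.34, III = 0.23, IV = 0.25)
    ),
    population = list(
      annual_baseline_screeners = 1563556,
      horizon_years = 3L,
      prevalence_crc = prev[2],
      baseline_modality_mix = c(colonoscopy = 0.85, fit = 0.15)
    ),
    symptomatic = list(
      q_undiagnosed = NA_real_,
      source = "calibrated"
    ),
    ci_ranges = list(
      colonoscopy_sensitivity = c(low = 0.90, point = 0.95, high = 1.00),
      prevalence_crc = c(low = prev[1], point = prev[2], high = prev[3]),
      fit_sensitivity = c(low = 0.69, point = 0.79, high = 0.85),
      fit_positivity = c(low = 0.063, point = 0.07, high = 0.077),
      fit_adherence = c(low = 0.52, point = 0.65, high = 0.78)
    )
  )
  # degenerate ranges for the stage proportions (published without CIs)
  for (route in STAGE_ROUTES) {
    for (s in STAGE_NAMES) {
      v <- unname(params$stages[[route]][s])
      params$ci_ranges[[paste("stage", route, s, sep = "_")]] <-
        c(low = v, point = v, high = v)
    }
  }
  class(params) <- "crc_params"
  validate_parameters(params)
}

#' Validate a parameter set
#'
#' Checks every structural invariant of a `crc_params` object: proportions in
#' \eqn{[0,1]}, stage distributions summing to 1 within 0.005, a positive
#' population and horizon, a baseline modality mix summing to 1, and CI
#' ranges bracketing their point values. Errors name the offending field.
#'
#' @param params A `crc_params` object (or plain list with the same shape).
#' @return The validated object, invisibly classed `crc_params`.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
  }
  chk_prop <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      fail(field, "must be a single proportion in [0, 1]")
    }
  }
  for (m in c("colonoscopy", "fit")) {
    t <- params$tests[[m]]
    if (is.null(t)) fail(paste0("tests$", m), "missing")
    chk_prop(t$sensitivity_crc, paste0("tests$", m, "$sensitivity_crc"))
    chk_prop(t$diagnostic_adherence, paste0("tests$", m, "$diagnostic_adherence"))
    if (!is.null(t$positivity_rate) && !is.na(t$positivity_rate)) {
      chk_prop(t$positivity_rate, paste0("tests$", m, "$positivity_rate"))
    }
    if (t$sensitivity_crc * t$diagnostic_adherence > 1) {
      fail(paste0("tests$", m), "sensitivity x adherence exceeds 1")
    }
  }
  for (route in STAGE_ROUTES) {
    p <- params$stages[[route]]
    if (is.null(p) || length(p) != 4L || !all(STAGE_NAMES %in% names(p))) {
      fail(paste0("stages$", route), "must hold four proportions named I-IV")
    }
    if (any(p < 0 | p > 1)) {
      fail(paste0("stages$", route), "stage proportions must lie in [0, 1]")
    }
    if (abs(sum(p) - 1) > 0.005) {
      fail(paste0("stages$", route),
           sprintf("stage proportions sum to %.4f, not 1 (tolerance 0.005)", sum(p)))
    }
  }
  pop <- params$population
  if (!is.numeric(pop$annual_baseline_screeners) ||
      pop$annual_baseline_screeners <= 0) {
    fail("population$annual_baseline_screeners", "must be > 0")
  }
  if (!is.numeric(pop$horizon_years) || pop$horizon_years < 1) {
    fail("population$horizon_years", "must be >= 1")
  }
  if (!is.numeric(pop$prevalence_crc) || pop$prevalence_crc <= 0 ||
      pop$prevalence_crc >= 1) {
    fail("population$prevalence_crc", "must lie in (0, 1)")
  }
  mix <- pop$baseline_modality_mix
  if (length(mix) != 2L || abs(sum(mix) - 1) > 1e-8) {
    fail("population$baseline_modality_mix", "must sum to 1")
  }
  q <- params$symptomatic$q_undiagnosed
  if (!is.na(q)) chk_prop(q, "symptomatic$q_undiagnosed")
  if (!params$symptomatic$source %in% c("calibrated", "user_supplied")) {
    fail("symptomatic$source", "must be 'calibrated' or 'user_supplied'")
  }
  for (nm in names(params$ci_ranges)) {
    r <- params$ci_ranges[[nm]]
    if (length(r) != 3L || !all(c("low", "point", "high") %in% names(r))) {
      fail(paste0("ci_ranges$", nm), "must be a (low, point, high) triple")
    }
    if (!(r["low"] <= r["point"] && r["point"] <= r["high"])) {
      fail(paste0("ci_ranges$", nm), "must satisfy low <= point <= high")
    }
  }
  class(params) <- "crc_params"
  invisible(params)
}

#' Set the symptomatic-presentation fraction
#'
#' @param params A `crc_params` object.
#' @param symptomatic Either a number in \eqn{[0,1]} or a list as returned by
#'   [calibrate_symptomatic_fraction()].
#' @return The updated `crc_params` object.
#' @export
set_symptomatic_fraction <- function(params, symptomatic) {
  if (is.numeric(symptomatic)) {
    symptomatic <- list(q_undiagnosed = unname(symptomatic),
                        source = "user_supplied")
  }
  params$symptomatic <- symptomatic
  validate_parameters(params)
  params
}

# ---- file I/O --------------------------------------------------------------

# external config schema <-> internal crc_params structure
params_to_config <- function(params) {
  unname_num <- function(x) as.numeric(unname(x))
  list(
    colonoscopy = list(
      sensitivity = params$tests$colonoscopy$sensitivity_crc,
      sensitivity_ci = unname_num(params$ci_ranges$colonoscopy_sensitivity[c("low", "high")])
    ),
    fit = list(
      sensitivity = params$tests$fit$sensitivity_crc,
      sensitivity_ci = unname_num(params$ci_ranges$fit_sensitivity[c("low", "high")]),
      positivity = params$tests$fit$positivity_rate,
      positivity_ci = unname_num(params$ci_ranges$fit_positivity[c("low", "high")]),
      adherence = params$tests$fit$diagnostic_adherence,
      adherence_ci = unname_num(params$ci_ranges$fit_adherence[c("low", "high")])
    ),
    prevalence = params$population$prevalence_crc,
    prevalence_ci = unname_num(params$ci_ranges$prevalence_crc[c("low", "high")]),
    stages = lapply(params$stages, function(p) as.list(as.numeric(p))),
    population = list(
      annual_baseline_screeners = params$population$annual_baseline_screeners,
      horizon_years = as.integer(params$population$horizon_years),
      baseline_modality_mix = as.list(as.numeric(params$population$baseline_modality_mix))
    ),
    symptomatic = list(
      q_undiagnosed = params$symptomatic$q_undiagnosed,
      source = params$symptomatic$source
    )
  )
}

config_into_params <- function(cfg, params) {
  set_ci <- function(name, ci, field) {
    if (is.null(ci)) return()
    if (length(ci) != 2L) {
      stop(sprintf("invalid config field '%s': CI must be [low, high]", field),
           call. = FALSE)
    }
    params$ci_ranges[[name]][c("low", "high")] <<- as.numeric(ci)
  }
  if (!is.null(cfg$colonoscopy$sensitivity)) {
    params$tests$colonoscopy$sensitivity_crc <- cfg$colonoscopy$sensitivity
  }
  set_ci("colonoscopy_sensitivity", cfg$colonoscopy$sensitivity_ci,
         "colonoscopy$sensitivity_ci")
  if (!is.null(cfg$fit$sensitivity)) {
    params$tests$fit$sensitivity_crc <- cfg$fit$sensitivity
  }
  set_ci("fit_sensitivity", cfg$fit$sensitivity_ci, "fit$sensitivity_ci")
  if (!is.null(cfg$fit$positivity)) {
    params$tests$fit$positivity_rate <- cfg$fit$positivity
  }
  set_ci("fit_positivity", cfg$fit$positivity_ci, "fit$positivity_ci")
  if (!is.null(cfg$fit$adherence)) {
    params$tests$fit$diagnostic_adherence <- cfg$fit$adherence
  }
  set_ci("fit_adherence", cfg$fit$adherence_ci, "fit$adherence_ci")
  if (!is.null(cfg$prevalence)) {
    params$population$prevalence_crc <- cfg$prevalence
  }
  set_ci("prevalence_crc", cfg$prevalence_ci, "prevalence_ci")
  if (!is.null(cfg$stages)) {
    for (route in names(cfg$stages)) {
      if (!route %in% STAGE_ROUTES) {
        stop(sprintf("invalid config field 'stages$%s': unknown route", route),
             call. = FALSE)
      }
      p <- unlist(cfg$stages[[route]])
      if (length(p) != 4L) {
        stop(sprintf("invalid config field 'stages$%s': need four proportions",
                     route), call. = FALSE)
      }
      params$stages[[route]] <- stats::setNames(as.numeric(p), STAGE_NAMES)
      params$ci_ranges[paste("stage", route, STAGE_NAMES, sep = "_")] <-
        lapply(as.numeric(p), function(v) c(low = v, point = v, high = v))
    }
  }
  if (!is.null(cfg$population)) {
    for (f in c("annual_baseline_screeners", "horizon_years")) {
      if (!is.null(cfg$population[[f]])) params$population[[f]] <- cfg$population[[f]]
    }
    if (!is.null(cfg$population$baseline_modality_mix)) {
      params$population$baseline_modality_mix <-
        stats::setNames(as.numeric(unlist(cfg$population$baseline_modality_mix)),
                        c("colonoscopy", "fit"))
    }
  }
  if (!is.null(cfg$symptomatic)) {
    if (!is.null(cfg$symptomatic$q_undiagnosed)) {
      params$symptomatic$q_undiagnosed <- cfg$symptomatic$q_undiagnosed
      params$symptomatic$source <- "user_supplied"
    }
    if (!is.null(cfg$symptomatic$source)) {
      params$symptomatic$source <- cfg$symptomatic$source
    }
  }
  # keep point values of CI ranges in step with overridden points
  params$ci_ranges$colonoscopy_sensitivity["point"] <- params$tests$colonoscopy$sensitivity_crc
  params$ci_ranges$fit_sensitivity["point"] <- params$tests$fit$sensitivity_crc
  params$ci_ranges$fit_positivity["point"] <- params$tests$fit$positivity_rate
  params$ci_ranges$fit_adherence["point"] <- params$tests$fit$diagnostic_adherence
  params$ci_ranges$prevalence_crc["point"] <- params$population$prevalence_crc
  params
}

#' Load model parameters from a YAML or JSON config file
#'
#' Fields absent from the file fall back to [default_parameters()]; any
#' invariant violation (for example stage proportions that do not sum to 1)
#' is a fatal error naming the offending field. The schema is the one written
#' by [save_parameters()]; top-level keys are `colonoscopy`, `fit`,
#' `prevalence`, `stages`, `population` and `symptomatic`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `crc_params` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  params <- config_into_params(cfg, default_parameters())
  validate_parameters(params)
  params
}

#' Save model parameters to a YAML or JSON config file
#'
#' The written file round-trips through [load_parameters()] to an identical
#' parameter set, and a save–load–save cycle is byte-identical.
#'
#' @param params A `crc_params` object.
#' @param path Destination path; format chosen by extension (`.json` for
#'   JSON, anything else YAML).
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  validate_parameters(params)
  cfg <- params_to_config(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}

#' @export
print.crc_params <- function(x, ...) {
  cat("CRC screening model parameters\n")
  cat(sprintf("  colonoscopy: sensitivity %.3f\n",
              x$tests$colonoscopy$sensitivity_crc))
  cat(sprintf("  FIT: sensitivity %.3f, positivity %.3f, diagnostic adherence %.3f\n",
              x$tests$fit$sensitivity_crc, x$tests$fit$positivity_rate,
              x$tests$fit$diagnostic_adherence))
  cat(sprintf("  population: %s would-be screeners/year over %d years; CRC prevalence %.4f\n",
              format(x$population$annual_baseline_screeners, big.mark = ","),
              as.integer(x$population$horizon_years),
              x$population$prevalence_crc))
  cat(sprintf("  baseline modality mix: %.0f%% colonoscopy / %.0f%% FIT\n",
              100 * x$population$baseline_modality_mix[["colonoscopy"]],
              100 * x$population$baseline_modality_mix[["fit"]]))
  q <- x$symptomatic$q_undiagnosed
  cat(sprintf("  symptomatic fraction q: %s (%s)\n",
              if (is.na(q)) "unset" else sprintf("%.4f", q),
              x$symptomatic$source))
  for (route in STAGE_ROUTES) {
    cat(sprintf("  stages %-18s %s\n", paste0(route, ":"),
                paste(sprintf("%s %.1f%%", STAGE_NAMES, 100 * x$stages[[route]]),
                      collapse = ", ")))
  }
  invisible(x)
}
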