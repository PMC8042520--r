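# One-way (tornado) and probabilistic sensitivity analysis over the
# published 95% CI ranges.

# setters from ci_ranges names into a crc_params object
set_model_parameter <- function(params, name, value) {
  if (startsWith(name, "stage_")) {
    bits <- strsplit(sub("^stage_", "", name), "_(?=[IV]+$)", perl = TRUE)[[1]]
    params$stages[[bits[1]]][[bits[2]]] <- value
    return(params)
  }
  switch(name,
    colonoscopy_sensitivity = {
      params$tests$colonoscopy$sensitivity_crc <- value
    },
    fit_sensitivity = {
      params$tests$fit$sensitivity_crc <- value
    },
    fit_positivity = {
      params$tests$fit$positivity_rate <- value
    },
    fit_adherence = {
      params$tests$fit$diagnostic_adherence <- value
    },
    prevalence_crc = {
      params$population$prevalence_crc <- value
    },
    stop("unknown model parameter: ", name, call. = FALSE)
  )
  params
}

get_outcome <- function(outcomes, outcome) {
  if (!outcome %in% names(outcomes$totals)) {
    stop(sprintf("unknown outcome selector '%s'; available: %s", outcome,
                 paste(OUTCOME_NAMES, collapse = ", ")), call. = FALSE)
  }
  unname(outcomes$totals[outcome])
}

#' One-way (tornado) sensitivity analysis
#'
#' Sets each parameter in turn to the low and high bound of its 95% CI range,
#' all other parameters held at base case, and records the chosen outcome.
#' Results are ordered by swing (|outcome(high) - outcome(low)|) descending —
#' tornado order — with ties broken alphabetically by parameter name. The
#' symptomatic fraction `q` is held fixed at its base-case value unless
#' `recalibrate = TRUE`, in which case it is re-calibrated against
#' `symptom_target` on the analysis schedule for every perturbed run.
#'
#' @param params A `crc_params` object with `q_undiagnosed` set.
#' @param outcome Outcome selector, one of the `crc_outcomes` total names
#'   (e.g. `"total_cases"`, `"early_stage_cases"`).
#' @param schedule The `uptake_schedule` to analyse.
#' @param parameters Which parameters to vary; default: all with
#'   non-degenerate CI ranges.
#' @param recalibrate Re-calibrate `q` for each perturbed parameter set?
#' @param symptom_target Calibration target used when `recalibrate = TRUE`.
#' @return A `crc_tornado` data frame: `parameter`, `low`, `base`, `high`
#'   (parameter values), `outcome_low`, `outcome_base`, `outcome_high`,
#'   `swing`.
#' @export
one_way_sensitivity <- function(params, outcome = "total_cases", schedule,
                                parameters = NULL, recalibrate = FALSE,
                                symptom_target = 576) {
  validate_parameters(params)
  if (is.null(parameters)) {
    nondegen <- vapply(params$ci_ranges,
                       function(r) r[["high"]] > r[["low"]], logical(1))
    parameters <- names(params$ci_ranges)[nondegen]
  }
  base_run <- run_cohort(params, schedule)
  base_out <- get_outcome(base_run, outcome)
  eval_at <- function(name, value) {
    p <- set_model_parameter(params, name, value)
    if (recalibrate) {
      p <- set_symptomatic_fraction(
        p, calibrate_symptomatic_fraction(p, symptom_target, schedule))
    }
    get_outcome(run_cohort(p, schedule), outcome)
  }
  rows <- lapply(parameters, function(name) {
    r <- params$ci_ranges[[name]]
    lo <- eval_at(name, r[["low"]])
    hi <- eval_at(name, r[["high"]])
    data.frame(parameter = name, low = r[["low"]], base = r[["point"]],
               high = r[["high"]], outcome_low = lo, outcome_base = base_out,
               outcome_high = hi, swing = abs(hi - lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing, out$parameter), ]
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  attr(out, "scenario_id") <- attr(schedule, "scenario_id")
  class(out) <- c("crc_tornado", "data.frame")
  out
}

#' @export
print.crc_tornado <- function(x, ...) {
  cat(sprintf("One-way sensitivity of '%s' (scenario '%s'), tornado order\n",
              attr(x, "outcome"), attr(x, "scenario_id")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-26s [%g, %g]: outcome %12.1f .. %12.1f  (swing %.1f)\n",
                x$parameter[i], x$low[i], x$high[i], x$outcome_low[i],
                x$outcome_high[i], x$swing[i]))
  }
  invisible(x)
}

#' Tornado bar chart
#'
#' @param x A `crc_tornado` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.crc_tornado <- function(x, ...) {
  rng <- rbind(pmin(x$outcome_low, x$outcome_high),
               pmax(x$outcome_low, x$outcome_high)) - x$outcome_base[1]
  graphics::barplot(rng[2, rev(seq_len(nrow(x)))],
                    names.arg = rev(x$parameter), horiz = TRUE, las = 1,
                    xlab = sprintf("change in %s from base case", attr(x, "outcome")),
                    ...)
  graphics::barplot(rng[1, rev(seq_len(nrow(x)))], horiz = TRUE, add = TRUE,
                    names.arg = rep("", nrow(x)), ...)
  graphics::abline(v = 0)
  invisible(x)
}

# ---- beta fitting ----------------------------------------------------------

# Fit a beta distribution to a point estimate and 95% CI. Preferred fit
# matches the 2.5th/97.5th percentiles to the CI bounds; when a bound sits on
# the [0,1] boundary no proper beta can reach it, so the fit falls back to
# matching the mean to the point estimate and the one interior quantile.
beta_from_ci <- function(point, low, high) {
  if (low > point || high < point) {
    stop("CI must bracket the point estimate", call. = FALSE)
  }
  if (low < 0 || high > 1) stop("CI bounds outside [0, 1]", call. = FALSE)
  if (high - low <= 0) return(NULL)  # degenerate: no sampling
  eps <- 1e-9
  if (low <= eps || high >= 1 - eps) {
    # boundary CI: mean = point, match the interior quantile; the shape total
    # k is monotone in the quantile, so uniroot on log k
    interior_p <- if (high >= 1 - eps) 0.025 else 0.975
    target <- if (high >= 1 - eps) low else high
    f <- function(logk) {
      k <- exp(logk)
      stats::qbeta(interior_p, point * k, (1 - point) * k) - target
    }
    sol <- stats::uniroot(f, c(log(2), log(1e7)), tol = 1e-12)
    k <- exp(sol$root)
    return(c(shape1 = point * k, shape2 = (1 - point) * k))
  }
  # interior CI: least-squares match of both quantiles, moment-based start
  m <- point
  s <- (high - low) / (2 * stats::qnorm(0.975))
  k0 <- max(m * (1 - m) / s^2 - 1, 2)
  obj <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    (stats::qbeta(0.025, a, b) - low)^2 + (stats::qbeta(0.975, a, b) - high)^2
  }
  fit <- stats::optim(log(c(m * k0, (1 - m) * k0)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (sqrt(fit$value) > 0.01 * (high - low)) {
    stop(sprintf("infeasible beta fit for CI (%g, %g)", low, high),
         call. = FALSE)
  }
  c(shape1 = exp(fit$par[1]), shape2 = exp(fit$par[2]))
}

#' Probabilistic sensitivity analysis
#'
#' Every parameter with a non-degenerate CI range is given a beta
#' distribution fitted so its 2.5th/97.5th percentiles reproduce the
#' published CI (see `beta_from_ci`; betas are the natural choice since all
#' varied inputs are probabilities, and need no truncation). `n_draws` joint
#' parameter draws are propagated through [run_cohort()]; the symptomatic
#' fraction `q` is held at its base-case value. Stage-distribution
#' proportions are published without CIs and are not varied.
#'
#' @param params A `crc_params` object with `q_undiagnosed` set.
#' @param schedule The `uptake_schedule` to analyse.
#' @param n_draws Number of parameter draws (>= 2).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A `crc_psa` object: list with `summary` (per-outcome mean and
#'   2.5/50/97.5 percentiles), `outcomes` (draws x outcomes matrix),
#'   `draws` (draws x parameters matrix).
#' @export
probabilistic_sensitivity <- function(params, schedule, n_draws = 1000,
                                      seed = 1) {
  validate_parameters(params)
  if (n_draws < 2) stop("n_draws must be >= 2", call. = FALSE)
  nondegen <- vapply(params$ci_ranges,
                     function(r) r[["high"]] > r[["low"]], logical(1))
  varied <- names(params$ci_ranges)[nondegen]
  shapes <- lapply(varied, function(nm) {
    r <- params$ci_ranges[[nm]]
    beta_from_ci(r[["point"]], r[["low"]], r[["high"]])
  })
  names(shapes) <- varied

  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_draws, ncol = length(varied),
                  dimnames = list(NULL, varied))
  for (nm in varied) {
    draws[, nm] <- stats::rbeta(n_draws, shapes[[nm]]["shape1"],
                                shapes[[nm]]["shape2"])
  }
  outcomes <- matrix(NA_real_, nrow = n_draws, ncol = length(OUTCOME_NAMES),
                     dimnames = list(NULL, OUTCOME_NAMES))
  for (i in seq_len(n_draws)) {
    p <- params
    for (nm in varied) p <- set_model_parameter(p, nm, draws[i, nm])
    outcomes[i, ] <- run_cohort(p, schedule)$totals[OUTCOME_NAMES]
  }
  qs <- apply(outcomes, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              na.rm = TRUE)
  out <- list(
    scenario_id = attr(schedule, "scenario_id"),
    seed = seed, n_draws = n_draws,
    summary = data.frame(outcome = OUTCOME_NAMES,
                         mean = unname(colMeans(outcomes)),
                         p2.5 = unname(qs[1, ]), p50 = unname(qs[2, ]),
                         p97.5 = unname(qs[3, ])),
    outcomes = outcomes,
    draws = draws
  )
  class(out) <- "crc_psa"
  out
}

#' @export
print.crc_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis, scenario '%s': %d draws (seed %d)\n",
              x$scenario_id, x$n_draws, x$seed))
  key <- x$summary$outcome %in% c("screened_total", "total_cases",
                                  "screen_detected_total", "symptom_detected",
                                  "early_stage_cases")
  df <- x$summary[key, ]
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-24s mean %14.1f   95%% CI [%.1f, %.1f]\n",
                df$outcome[i], df$mean[i], df$p2.5[i], df$p97.5[i]))
  }
  invisible(x)
}
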