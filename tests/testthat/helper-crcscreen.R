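# Shared fixtures, built in code.

# default parameters with q calibrated on the baseline schedule
calibrated_default_params <- function(target = 576) {
  p <- default_parameters()
  set_symptomatic_fraction(
    p, calibrate_symptomatic_fraction(p, target, canonical_schedules()$baseline))
}

# randomized-but-valid parameter set; caller controls the RNG state
random_params <- function() {
  p <- default_parameters()
  p$tests$colonoscopy$sensitivity_crc <- runif(1, 0.5, 1)
  p$tests$fit$sensitivity_crc <- runif(1, 0.3, 0.95)
  p$tests$fit$diagnostic_adherence <- runif(1, 0.2, 1)
  p$tests$fit$positivity_rate <- runif(1, 0.03, 0.2)
  p$population$prevalence_crc <- runif(1, 0.0005, 0.05)
  p$population$annual_baseline_screeners <- round(runif(1, 1e4, 5e6))
  p$symptomatic <- list(q_undiagnosed = runif(1), source = "user_supplied")
  validate_parameters(p)
  p
}

# random 3-year schedule with exact yearly sums
random_schedule <- function(id = "random") {
  w <- matrix(rgamma(9, 1) + 1e-6, ncol = 3)
  w <- w / rowSums(w)
  uptake_schedule(id, w[, 1], w[, 2], w[, 3])
}

# hand-computed baseline quantities (independent of package internals):
# colonoscopy 3-yr screeners = 4,690,668 x 0.85; FIT = x 0.15; the
# undiagnosed pool is colonoscopy false negatives + FIT cancers not
# screen-detected (FIT detects with prob 0.79 x 0.65 = 0.5135)
baseline_pool_by_hand <- function() {
  4690668 * 0.85 * 0.008 * (1 - 0.95) +
    4690668 * 0.15 * 0.008 * (1 - 0.79 * 0.65)
}
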