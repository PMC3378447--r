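#' Define a simulation scenario
#'
#' A scenario fixes the data-generating mechanism for one Monte-Carlo
#' experiment: cohort size, log hazard ratios, the marginal distribution of
#' the phase-2 covariate, the surrogate noise, the administrative censoring
#' window and the subcohort size.
#'
#' The generated cohort has a binary phase-1 covariate `Z1 ~ Bernoulli(0.5)`,
#' a standard-normal phase-1 covariate `Z3`, and a phase-2 covariate `Z2`
#' standardized to zero mean and unit variance with `cor(Z2, Z3) = rho23`
#' and `Z2` independent of `Z1`.  Survival times are exponential with
#' subject rate `exp(beta1*Z1 + beta2*Z2 + beta3*Z3)`; censoring is
#' `Uniform(0, tau)`.  A surrogate `Z2_surr = Z2 + eps`,
#' `eps ~ N(0, sigma2_surr)`, is observed cohort-wide and drives the
#' stratification (tertiles of the surrogate crossed with tertiles of `Z3`
#' give 9 strata by default).
#'
#' @param N cohort size.
#' @param beta1,beta2,beta3 log hazard ratios of `Z1`, `Z2`, `Z3`.
#' @param z2_dist marginal law of `Z2`: `"normal"`, `"lognormal"`
#'   (exponentiated standard normal, standardized) or `"uniform"`
#'   (on `(-sqrt(3), sqrt(3))`); all have unit variance by construction.
#' @param rho23 target correlation between `Z2` and `Z3` (default 0.2).
#' @param sigma2_surr variance of the surrogate noise (default 1, giving
#'   `cor(Z2, Z2_surr)` close to 0.71).
#' @param tau upper bound of the uniform censoring time (default 0.025,
#'   giving an event probability near 3\% when all betas equal `log(2)`).
#' @param subcohort_size number of subjects sampled into the subcohort.
#' @param n_strata_per_axis number of quantile groups per stratification
#'   axis (default 3, i.e. tertiles, 9 strata in total).
#' @param seed optional integer seed used by [simulate_cohort()].
#' @return An object of class `scenario_config` (a validated list).
#' @seealso [simulate_cohort()], [draw_case_cohort()]
#' @export
#' @examples
#' cfg <- scenario_config(N = 2000, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' mean(cohort$event)
scenario_config <- function(N = 10000,
                            beta1 = log(2), beta2 = log(2), beta3 = log(2),
                            z2_dist = c("normal", "lognormal", "uniform"),
                            rho23 = 0.2, sigma2_surr = 1, tau = 0.025,
                            subcohort_size = 1000, n_strata_per_axis = 3,
                            seed = NULL) {
  z2_dist <- match.arg(z2_dist)
  if (!is.numeric(N) || length(N) != 1L || N <= 0 || N != round(N))
    stop("`N` must be a positive integer")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("`tau` must be positive")
  if (abs(rho23) >= 1) stop("`rho23` must be in (-1, 1)")
  if (sigma2_surr < 0) stop("`sigma2_surr` must be non-negative")
  if (subcohort_size < 1 || subcohort_size > N)
    stop("`subcohort_size` must be in [1, N]")
  if (n_strata_per_axis < 1) stop("`n_strata_per_axis` must be >= 1")
  cfg <- list(N = as.integer(N), beta1 = beta1, beta2 = beta2, beta3 = beta3,
              z2_dist = z2_dist, rho23 = rho23, sigma2_surr = sigma2_surr,
              tau = tau, subcohort_size = as.integer(subcohort_size),
              n_strata_per_axis = as.integer(n_strata_per_axis),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  # the latent Gaussian correlation that yields cor(Z2, Z3) = rho23 after
  # transforming the latent normal to the requested marginal
  r <- switch(z2_dist,
              normal    = rho23,
              lognormal = rho23 * sqrt(exp(1) - 1),
              uniform   = rho23 * sqrt(pi / 3))
  if (abs(r) >= 1) stop("`rho23` not attainable for this z2_dist")
  cfg$latent_rho <- r
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Case-cohort simulation scenario\n")
  cat(sprintf("  N = %d, subcohort = %d, tau = %g\n",
              x$N, x$subcohort_size, x$tau))
  cat(sprintf("  beta = (%.4f, %.4f, %.4f), Z2 ~ %s, rho23 = %g\n",
              x$beta1, x$beta2, x$beta3, x$z2_dist, x$rho23))
  cat(sprintf("  surrogate noise var = %g, strata = %d x %d%s\n",
              x$sigma2_surr, x$n_strata_per_axis, x$n_strata_per_axis,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Read or write a scenario as a flat JSON file
#'
#' @param config a `scenario_config`.
#' @param path file path.
#' @return `read_scenario()` returns a `scenario_config`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  x <- unclass(config)
  x$latent_rho <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(scenario_config, x)
}
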