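# Monte-Carlo study harness: replicate the simulation experiments and
# summarize bias, efficiency and power per estimator

replicate_seed <- function(seed, rep) {
  s <- (as.double(seed) + as.double(rep)) %% 2147483647
  as.integer(s)
}

#' Monte-Carlo study of the hazard-ratio estimators
#'
#' For each replicate: simulate a full cohort; fit the full-cohort model
#' (gold standard); draw a stratified case-cohort sample; fit the Borgan II
#' weighted estimator; impute `M` completed cohorts and pool the fits by
#' Rubin's rules.  Summaries per estimator and parameter: mean estimate,
#' mean of estimated SEs, empirical SD of the estimates, MSE against the
#' scenario's true value, and the percent of replicates rejecting the null
#' that the coefficient is zero at the 5\% level.
#'
#' Per-replicate randomness is seeded deterministically from
#' `config$seed + replicate`, so results are reproducible and independent
#' of execution order.
#'
#' @param config a [scenario_config()] (its `seed` drives the study).
#' @param n_reps number of replicates (>= 2).
#' @param M imputations per replicate.
#' @param covariates hazard-model covariates.
#' @param spec imputation model specification.
#' @param case_entry risk-set convention for the weighted fit, see
#'   [fit_borgan()].
#' @param max_fail_frac abort if more than this fraction of replicates fail.
#' @return an `estimation_study`: `summary` (data.frame), `draws` (per-
#'   replicate estimate/SE arrays), `fmi` (per-replicate MI fractions of
#'   missing information), `n_failed`, `config`.
#' @export
run_estimation_study <- function(config, n_reps, M = 5L,
                                 covariates = c("Z1", "Z2", "Z3"),
                                 spec = imputation_spec(),
                                 case_entry = "full",
                                 max_fail_frac = 0.2) {
  stopifnot(inherits(config, "scenario_config"), n_reps >= 2)
  seed0 <- if (is.null(config$seed)) 0L else config$seed
  estimators <- c("full", "mi", "weighted")
  p <- length(covariates)
  est <- se <- rej <- array(NA_real_, dim = c(n_reps, 3, p),
                            dimnames = list(NULL, estimators, covariates))
  fmi <- matrix(NA_real_, n_reps, p, dimnames = list(NULL, covariates))
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    ok <- tryCatch({
      set.seed(replicate_seed(seed0, r))
      cohort <- simulate_cohort(modifyList_config(config, seed = NULL))
      f_full <- fit_cox(cohort, covariates)
      est[r, "full", ] <- f_full$coef
      se[r, "full", ] <- sqrt(diag(f_full$cov_model))
      cc <- draw_case_cohort(cohort, config$subcohort_size)
      f_w <- fit_borgan(cc, covariates, case_entry = case_entry)
      est[r, "weighted", ] <- f_w$coef
      se[r, "weighted", ] <- sqrt(diag(f_w$cov_robust))
      impfit <- fit_imputation_model(cc, spec)
      imps <- draw_imputations(cc, impfit, M)
      fits <- lapply(imps, fit_cox, covariates = covariates)
      pooled <- pool_rubin(lapply(fits, coef),
                           lapply(fits, vcov, type = "model"))
      est[r, "mi", ] <- pooled$theta
      se[r, "mi", ] <- pooled$se
      fmi[r, ] <- pooled$fmi
      for (k in seq_len(p))
        rej[r, "mi", k] <- wald_test(pooled, 0, k)$reject
      TRUE
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) n_failed <- n_failed + 1L
  }
  if (n_failed > max_fail_frac * n_reps)
    stop(n_failed, " of ", n_reps, " replicates failed")
  # normal-reference Wald rejection for the single-fit estimators
  rej[, "full", ] <- abs(est[, "full", ] / se[, "full", ]) > qnorm(0.975)
  rej[, "weighted", ] <- abs(est[, "weighted", ] / se[, "weighted", ]) > qnorm(0.975)
  true <- c(Z1 = config$beta1, Z2 = config$beta2, Z3 = config$beta3)
  rows <- list()
  for (e in estimators) for (k in seq_len(p)) {
    x <- est[, e, k]; s <- se[, e, k]
    tv <- if (covariates[k] %in% names(true)) true[[covariates[k]]] else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      estimator = e, parameter = covariates[k], true = tv,
      est = mean(x, na.rm = TRUE), se_hat = mean(s, na.rm = TRUE),
      se_emp = sd(x[!is.na(x)]),
      mse = if (is.na(tv)) NA_real_ else mean((x - tv)^2, na.rm = TRUE),
      reject_pct = 100 * mean(rej[, e, k], na.rm = TRUE),
      n_reps = sum(!is.na(x)))
  }
  out <- list(summary = do.call(rbind, rows),
              draws = list(est = est, se = se, reject = rej),
              fmi = fmi, n_failed = n_failed, config = config, M = M)
  class(out) <- "estimation_study"
  out
}

# copy a scenario with fields replaced (rebuilds to revalidate)
modifyList_config <- function(config, ...) {
  x <- unclass(config)
  x$latent_rho <- NULL
  repl <- list(...)
  for (nm in names(repl)) x[nm] <- repl[nm]   # keeps NULLs
  do.call(scenario_config, x)
}

#' @export
print.estimation_study <- function(x, ...) {
  cat(sprintf("Estimation study: %d replicates (%d failed), M = %d\n",
              x$summary$n_reps[1] + x$n_failed, x$n_failed, x$M))
  s <- x$summary
  s[, c("true", "est", "se_hat", "se_emp", "mse")] <-
    round(s[, c("true", "est", "se_hat", "se_emp", "mse")], 4)
  s$reject_pct <- round(s$reject_pct, 1)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Monte-Carlo study of the predictive-ability estimators
#'
#' For each replicate: simulate a full cohort and (as requested) compute
#' the full-cohort metrics, the naive case-cohort metrics and the
#' MI-pooled metrics for each subcohort size.  Metrics: `C1`, `C2`,
#' `delta`, `NRI`, `IDI`, with the bootstrap-within-imputation variance for
#' `delta` when `n_boot > 0`.  Summaries per analysis and metric: mean
#' estimate, mean estimated SE, empirical SD, percent of replicates
#' rejecting the zero null.
#'
#' @param config a [scenario_config()].
#' @param n_reps replicates (>= 2).
#' @param analyses subset of `c("full", "naive", "mi")`.
#' @param subcohort_sizes subcohort sizes for the naive / MI analyses.
#' @param M imputations.
#' @param n_boot bootstrap resamples for the SE of `delta` (0 = skip SEs
#'   and tests for `delta`).
#' @param cutpoints NRI risk categories (probability cut-points).
#' @param horizon risk-prediction horizon; defaults to `config$tau`.
#' @param covs1,covs2 nested model covariates.
#' @param spec imputation specification.
#' @param max_fail_frac abort if more than this fraction of replicates fail.
#' @return a `discrimination_study`: `summary` data.frame and raw `draws`.
#' @export
run_discrimination_study <- function(config, n_reps,
                                     analyses = c("full", "naive", "mi"),
                                     subcohort_sizes = c(300L, 1000L),
                                     M = 5L, n_boot = 100L,
                                     cutpoints = c(0.025, 0.05),
                                     horizon = config$tau,
                                     covs1 = c("Z1", "Z3"),
                                     covs2 = c("Z1", "Z2", "Z3"),
                                     spec = imputation_spec(),
                                     max_fail_frac = 0.2) {
  stopifnot(inherits(config, "scenario_config"), n_reps >= 2)
  analyses <- match.arg(analyses, several.ok = TRUE)
  seed0 <- if (is.null(config$seed)) 0L else config$seed
  labels <- character(0)
  if ("full" %in% analyses) labels <- "full"
  for (sz in subcohort_sizes) {
    if ("naive" %in% analyses) labels <- c(labels, paste0("cc", sz))
    if ("mi" %in% analyses) labels <- c(labels, paste0("mi", sz))
  }
  metrics <- c("c1", "c2", "delta", "nri", "idi")
  est <- se <- rej <- array(NA_real_,
                            dim = c(n_reps, length(labels), length(metrics)),
                            dimnames = list(NULL, labels, metrics))
  n_failed <- 0L
  grab <- function(res, r, lab) {
    for (m in metrics) {
      x <- res[[m]]
      if (is.null(x)) next
      est[r, lab, m] <<- x$estimate
      se[r, lab, m] <<- x$se
      if (m %in% c("delta", "nri", "idi") &&
          !is.null(x$reject) && !is.na(x$reject))
        rej[r, lab, m] <<- as.numeric(x$reject)
    }
  }
  for (r in seq_len(n_reps)) {
    ok <- tryCatch({
      set.seed(replicate_seed(seed0, r))
      cohort <- simulate_cohort(modifyList_config(config, seed = NULL))
      if ("full" %in% analyses)
        grab(full_discrimination(cohort, covs1, covs2, horizon,
                                 n_boot = n_boot, cutpoints = cutpoints),
             r, "full")
      for (sz in subcohort_sizes) {
        if (!any(c("naive", "mi") %in% analyses)) break
        cc <- draw_case_cohort(cohort, sz)
        if ("naive" %in% analyses)
          grab(naive_discrimination(cc, covs1, covs2, horizon,
                                    n_boot = n_boot, cutpoints = cutpoints),
               r, paste0("cc", sz))
        if ("mi" %in% analyses)
          grab(mi_discrimination(cc, spec, covs1, covs2, horizon, M = M,
                                 n_boot = n_boot, cutpoints = cutpoints),
               r, paste0("mi", sz))
      }
      TRUE
    }, error = function(e) {
      warning("replicate ", r, " failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) n_failed <- n_failed + 1L
  }
  if (n_failed > max_fail_frac * n_reps)
    stop(n_failed, " of ", n_reps, " replicates failed")
  rows <- list()
  for (l in labels) for (m in metrics) {
    x <- est[, l, m]
    if (all(is.na(x))) next
    rows[[length(rows) + 1L]] <- data.frame(
      analysis = l, metric = m,
      est = mean(x, na.rm = TRUE),
      se_hat = mean(se[, l, m], na.rm = TRUE),
      se_emp = sd(x[!is.na(x)]),
      reject_pct = if (all(is.na(rej[, l, m]))) NA_real_
                   else 100 * mean(rej[, l, m], na.rm = TRUE),
      n_reps = sum(!is.na(x)))
  }
  out <- list(summary = do.call(rbind, rows),
              draws = list(est = est, se = se, reject = rej),
              n_failed = n_failed, config = config, M = M, n_boot = n_boot,
              cutpoints = cutpoints, horizon = horizon)
  class(out) <- "discrimination_study"
  out
}

#' @export
print.discrimination_study <- function(x, ...) {
  cat(sprintf("Discrimination study: %d replicates (%d failed), M = %d, %d bootstraps\n",
              max(x$summary$n_reps) + x$n_failed, x$n_failed, x$M, x$n_boot))
  s <- x$summary
  s[, c("est", "se_hat", "se_emp")] <- round(s[, c("est", "se_hat", "se_emp")], 4)
  s$reject_pct <- round(s$reject_pct, 1)
  print(s, row.names = FALSE)
  invisible(x)
}
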