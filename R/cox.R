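# proportional-hazards engine: (weighted) partial likelihood, Breslow ties

#' Fit a proportional-hazards model by (weighted) partial likelihood
#'
#' Newton-type maximization of the Cox partial likelihood with Breslow tie
#' handling.  Convergence is declared when the maximum absolute score falls
#' below `1e-8` or the relative log-likelihood change falls below `1e-10`.
#' With sampling `weights` the weighted partial likelihood is maximized and
#' a robust (influence-function / dfbeta) sandwich covariance is reported
#' alongside the model-based inverse information.  Rows with weight zero
#' are excluded entirely (they may carry missing covariates).
#'
#' @param data a data.frame with columns `X` (follow-up time) and `event`
#'   (0/1), plus the covariates.
#' @param covariates character vector of covariate column names.
#' @param weights optional non-negative sampling weights (one per row of
#'   `data`), e.g. from [borgan_weights()]; `NULL` means unweighted.
#' @param entry optional left-truncation (delayed entry) times; a subject is
#'   at risk on `(entry, X]`.  Default: all zero.
#' @param init optional starting coefficients (warm start, e.g. for
#'   bootstrap refits).
#' @param minimal if `TRUE`, return only coefficients, model covariance and
#'   the linear predictor (skips robust covariance, residuals and the
#'   baseline; used internally by the bootstrap).
#' @return An object of class `cox_fit`: `coef`, `cov_model`, `cov_robust`,
#'   `loglik`, `loglik0`, `baseline` (data.frame of event times with Breslow
#'   hazard increments and cumulative hazard), `n`, `n_events`, `converged`.
#' @export
#' @examples
#' cfg <- scenario_config(N = 1500, seed = 42)
#' cohort <- simulate_cohort(cfg)
#' fit <- fit_cox(cohort, c("Z1", "Z2", "Z3"))
#' coef(fit)
fit_cox <- function(data, covariates, weights = NULL, entry = NULL,
                    init = NULL, minimal = FALSE) {
  stopifnot(all(c("X", "event") %in% names(data)))
  miss <- setdiff(covariates, names(data))
  if (length(miss)) stop("unknown covariates: ", paste(miss, collapse = ", "))
  n_all <- nrow(data)
  if (is.null(weights)) weights <- rep(1, n_all)
  if (length(weights) != n_all) stop("`weights` must match nrow(data)")
  if (any(weights < 0)) stop("`weights` must be non-negative")
  has_entry <- !is.null(entry)
  if (!has_entry) entry <- rep(0, n_all)

  keep <- weights > 0
  d <- data[keep, , drop = FALSE]
  w <- weights[keep]
  en <- entry[keep]
  Xm <- as.matrix(d[, covariates, drop = FALSE])
  if (anyNA(Xm)) stop("missing covariate values among rows with weight > 0")
  if (any(d$X <= 0)) stop("follow-up times must be positive")
  if (sum(d$event == 1) < 1) stop("at least one event is required")

  ord <- order(d$X)
  res <- cox_fit_cpp(as.numeric(d$X[ord]), as.numeric(en[ord]),
                     as.integer(d$event[ord]),
                     Xm[ord, , drop = FALSE], as.numeric(w[ord]),
                     has_entry,
                     if (is.null(init)) numeric(0) else as.numeric(init),
                     minimal)
  if (!res$converged)
    warning("partial-likelihood maximization did not converge (max |score| = ",
            format(max(abs(res$score)), digits = 3), ")")
  else if (max(abs(res$coef)) > 15)
    warning("complete separation suspected: a coefficient diverged beyond ",
            "+-15 on a likelihood plateau")
  coefs <- setNames(as.numeric(res$coef), covariates)
  dimnames(res$var_model) <- dimnames(res$var_robust) <-
    list(covariates, covariates)
  out <- list(coef = coefs,
              cov_model = res$var_model,
              cov_robust = res$var_robust,
              loglik = res$loglik, loglik0 = res$loglik0,
              baseline = if (minimal) NULL else
                data.frame(time = as.numeric(res$base_time),
                           hazard = as.numeric(res$base_haz),
                           cumhaz = cumsum(as.numeric(res$base_haz))),
              n = nrow(d), n_events = res$n_events,
              converged = res$converged, weighted = !all(w == w[1]) || has_entry,
              covariates = covariates, iter = res$iter, minimal = minimal)
  class(out) <- "cox_fit"
  out
}

#' @export
coef.cox_fit <- function(object, ...) object$coef

#' Covariance of a `cox_fit`
#'
#' @param object a `cox_fit`.
#' @param type `"model"` (inverse information) or `"robust"` (dfbeta
#'   sandwich).  Weighted fits should use the robust covariance.
#' @param ... unused.
#' @return covariance matrix.
#' @export
vcov.cox_fit <- function(object, type = c("model", "robust"), ...) {
  type <- match.arg(type)
  if (type == "model") object$cov_model else object$cov_robust
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Proportional-hazards fit (%s), %d subjects, %d events\n",
              if (x$weighted) "weighted partial likelihood" else "partial likelihood",
              x$n, x$n_events))
  se_m <- sqrt(diag(x$cov_model))
  se_r <- sqrt(diag(x$cov_robust))
  tab <- data.frame(coef = x$coef, `exp(coef)` = exp(x$coef),
                    se = se_m, robust_se = se_r, check.names = FALSE)
  print(round(tab, 4))
  cat(sprintf("loglik = %.3f (null %.3f), converged: %s\n",
              x$loglik, x$loglik0, x$converged))
  invisible(x)
}

#' Summarize a `cox_fit` as a plain list (JSON-friendly)
#'
#' @param fit a `cox_fit`.
#' @param robust use the robust covariance for SEs and CIs.
#' @param level confidence level.
#' @return list with coef, se, CI bounds and loglik.
#' @export
cox_fit_summary <- function(fit, robust = fit$weighted, level = 0.95) {
  se <- sqrt(diag(if (robust) fit$cov_robust else fit$cov_model))
  zq <- qnorm(1 - (1 - level) / 2)
  list(covariates = fit$covariates,
       coef = unname(fit$coef), se = unname(se),
       hr = unname(exp(fit$coef)),
       ci_lower = unname(exp(fit$coef - zq * se)),
       ci_upper = unname(exp(fit$coef + zq * se)),
       loglik = fit$loglik, n = fit$n, n_events = fit$n_events,
       converged = fit$converged, robust = robust)
}

#' Borgan II stratified inverse-sampling-fraction weights
#'
#' Weight 1 for every case; for a non-case subcohort member of stratum `s`,
#' the number of cohort non-cases in `s` divided by the number of sampled
#' (subcohort) non-cases in `s`; weight 0 for non-cases outside the
#' subcohort.  Within each stratum the non-case weights therefore sum to
#' the cohort non-case count.
#'
#' @param data a cohort table carrying `event`, `in_subcohort` and
#'   `stratum` for the whole phase-1 cohort.
#' @return numeric weight vector aligned with `data` rows.
#' @export
borgan_weights <- function(data) {
  stopifnot(all(c("event", "in_subcohort", "stratum") %in% names(data)))
  w <- numeric(nrow(data))
  w[data$event == 1L] <- 1
  noncase <- data$event == 0L
  for (s in unique(data$stratum)) {
    in_s <- data$stratum == s & noncase
    n_coh <- sum(in_s)
    n_sub <- sum(in_s & data$in_subcohort == 1L)
    if (n_coh > 0 && n_sub == 0)
      stop("stratum ", s, " has cohort non-cases but no sampled non-cases")
    if (n_sub > 0)
      w[in_s & data$in_subcohort == 1L] <- n_coh / n_sub
  }
  w
}

#' Borgan II weighted fit on a case-cohort sample
#'
#' Convenience wrapper: computes [borgan_weights()] and fits the weighted
#' partial likelihood on the completely observed subjects.  By default
#' every observed subject is at risk over their whole follow-up
#' (`case_entry = "full"`); `case_entry = "at_failure"` is the finer
#' variant in which a case outside the subcohort enters the risk set only
#' just before its own failure (implemented by left truncation at
#' `X * (1 - 1e-9)`).
#'
#' @param data a case-cohort cohort table (all phase-1 rows, masked `Z2`).
#' @param covariates covariate names for the hazard model.
#' @param case_entry `"full"` or `"at_failure"`.
#' @return a `cox_fit`; use the robust covariance for inference.
#' @export
fit_borgan <- function(data, covariates,
                       case_entry = c("full", "at_failure")) {
  case_entry <- match.arg(case_entry)
  w <- borgan_weights(data)
  entry <- NULL
  if (case_entry == "at_failure") {
    entry <- rep(0, nrow(data))
    late <- data$event == 1L & data$in_subcohort == 0L
    entry[late] <- data$X[late] * (1 - 1e-9)
  }
  fit_cox(data, covariates, weights = w, entry = entry)
}

#' Predicted event probability at a fixed horizon
#'
#' Returns `1 - S(horizon | covariates)` from the Breslow baseline of a
#' fitted model: `1 - exp(-Lambda0(horizon) * exp(lp))`, with the step
#' baseline evaluated right-continuously.  Strictly increasing in the
#' linear predictor.
#'
#' @param fit a `cox_fit`.
#' @param data data.frame containing the model covariates.
#' @param horizon positive prediction time.
#' @return vector of probabilities in `[0, 1]`.
#' @export
predicted_risk <- function(fit, data, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("`horizon` must be a positive scalar")
  Xm <- as.matrix(data[, fit$covariates, drop = FALSE])
  if (anyNA(Xm)) stop("missing covariate values")
  lp <- drop(Xm %*% fit$coef)
  L0 <- with(fit$baseline, if (any(time <= horizon))
    max(cumhaz[time <= horizon]) else 0)
  1 - exp(-L0 * exp(lp))
}

#' Linear predictor of a `cox_fit` on new data
#'
#' @param object a `cox_fit`.
#' @param newdata data.frame with the model covariates.
#' @param ... unused.
#' @return numeric vector of linear predictors (risk scores).
#' @export
predict.cox_fit <- function(object, newdata, ...) {
  Xm <- as.matrix(newdata[, object$covariates, drop = FALSE])
  drop(Xm %*% object$coef)
}
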