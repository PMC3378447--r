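# predictive ability: Harrell's C, delta C, NRI, IDI, and their MI pooling

#' Harrell's concordance index with the usable-pair rule
#'
#' Usable pairs are formed by two uncensored subjects with distinct event
#' times, or by an uncensored subject and a subject censored at or after
#' the uncensored subject's event.  A pair is concordant when the higher
#' risk score belongs to the earlier event time; score ties count one half.
#' C is the proportion of concordant pairs among usable pairs.  The
#' standard error comes from the unconditional per-subject U-statistic
#' decomposition (each subject's concordant and usable totals), with a
#' leave-one-out jackknife available as a cross-check.
#'
#' @param time follow-up times.
#' @param event 0/1 event indicators (at least one event).
#' @param score risk scores (higher = higher risk), e.g. a linear predictor.
#' @param se_method `"ustat"` (default) or `"jackknife"`.
#' @param variance set `FALSE` to skip the SE (uses an O(n log n)
#'   rank-tree counting path; the bootstrap uses this).
#' @return a `concordance_result`: `c`, `se`, `n_usable`, `n_concordant`.
#' @export
#' @examples
#' harrell_c(c(1, 2, 3, 4), c(1, 1, 0, 1), c(0.9, 0.7, 0.5, 0.8))
harrell_c <- function(time, event, score,
                      se_method = c("ustat", "jackknife"),
                      variance = TRUE) {
  se_method <- match.arg(se_method)
  n <- length(time)
  stopifnot(length(event) == n, length(score) == n)
  if (sum(event == 1) < 1) stop("at least one event is required")
  res <- if (variance)
    concordance_cpp(as.numeric(time), as.integer(event), as.numeric(score))
  else
    concordance_counts_cpp(as.numeric(time), as.integer(event),
                           as.numeric(score))
  if (res$usable == 0) stop("no usable pairs")
  cval <- res$concordant / res$usable
  if (res$tied_score == res$usable)
    warning("constant risk scores: concordance undefined, reporting 0.5")
  se <- NA_real_
  if (variance) {
    P <- res$P_i; Q <- res$Q_i
    if (se_method == "ustat") {
      # C = sum(P_i)/sum(Q_i); delta-method variance of the ratio of
      # two degree-2 U-statistics from per-subject totals
      se <- 2 * sqrt(sum((P - cval * Q)^2)) / sum(Q)
    } else {
      ci <- (res$concordant - P) / (res$usable - Q)
      ci[!is.finite(ci)] <- cval
      se <- sqrt((n - 1) / n * sum((ci - mean(ci))^2))
    }
  }
  out <- list(c = cval, se = se, n_usable = res$usable,
              n_concordant = res$concordant, n_tied_score = res$tied_score,
              se_method = se_method)
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.4f (SE %.4f), %g concordant / %g usable pairs\n",
              x$c, x$se, x$n_concordant, x$n_usable))
  invisible(x)
}

# one completed data set: both model fits and every metric; shared by the
# full-cohort, naive and per-imputation computations
single_discrimination <- function(data, covs1, covs2, horizon,
                                  n_boot = 100L, cutpoints = c(0.025, 0.05),
                                  compute_nri = TRUE) {
  fit1 <- fit_cox(data, covs1)
  fit2 <- fit_cox(data, covs2)
  c1 <- harrell_c(data$X, data$event, predict(fit1, data))
  c2 <- harrell_c(data$X, data$event, predict(fit2, data))
  delta <- c2$c - c1$c
  boot <- delta_c_bootstrap(data, covs1, covs2, n_boot,
                            init1 = fit1$coef, init2 = fit2$coef)
  p1 <- predicted_risk(fit1, data, horizon)
  p2 <- predicted_risk(fit2, data, horizon)
  nri_res <- if (compute_nri) nri(p1, p2, data$event, cutpoints) else NULL
  idi_res <- idi(p1, p2, data$event)
  list(c1 = c1, c2 = c2, delta = delta, delta_se = boot$se,
       n_boot_used = boot$n_used, nri = nri_res, idi = idi_res,
       fit1 = fit1, fit2 = fit2)
}

delta_c_bootstrap <- function(data, covs1, covs2, n_boot,
                              init1 = NULL, init2 = NULL) {
  if (n_boot < 1) return(list(se = NA_real_, n_used = 0L, deltas = numeric(0)))
  n <- nrow(data)
  deltas <- numeric(n_boot)
  redraws <- 0L
  n_nonconv <- 0L
  # raw arrays: resampling + refitting must not pay data.frame costs
  tim <- as.numeric(data$X)
  ev <- as.integer(data$event)
  X1m <- as.matrix(data[, covs1, drop = FALSE])
  X2m <- as.matrix(data[, covs2, drop = FALSE])
  zeros <- numeric(n)
  ones <- rep(1, n)
  if (is.null(init1)) init1 <- numeric(0)
  if (is.null(init2)) init2 <- numeric(0)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (any(ev[idx] == 1L)) break
      redraws <- redraws + 1L
      if (redraws > 100L) stop("bootstrap cannot find a resample with events")
    }
    o <- idx[order(tim[idx])]
    tb <- tim[o]; eb <- ev[o]
    f1 <- cox_fit_cpp(tb, zeros, eb, X1m[o, , drop = FALSE], ones, FALSE,
                      as.numeric(init1), TRUE)
    f2 <- cox_fit_cpp(tb, zeros, eb, X2m[o, , drop = FALSE], ones, FALSE,
                      as.numeric(init2), TRUE)
    if (!f1$converged || !f2$converged) n_nonconv <- n_nonconv + 1L
    cb1 <- concordance_counts_cpp(tb, eb, as.numeric(f1$lp))
    cb2 <- concordance_counts_cpp(tb, eb, as.numeric(f2$lp))
    deltas[b] <- cb2$concordant / cb2$usable - cb1$concordant / cb1$usable
  }
  if (redraws > 0)
    message(redraws, " bootstrap resample(s) without events were redrawn")
  if (n_nonconv > 0)
    warning(n_nonconv, " bootstrap refit(s) did not fully converge")
  list(se = sd(deltas), n_used = n_boot, deltas = deltas)
}

#' Difference in Harrell's C between nested models, bootstrap SE
#'
#' Fits the model without (`covs1`) and with (`covs2`) the added variable
#' on a completely observed data set, reports `delta = C2 - C1`, and
#' estimates its standard error by resampling subjects with replacement and
#' refitting both models on every resample (resamples without events are
#' redrawn).
#'
#' @param data a complete data set (e.g. a reconstructed cohort).
#' @param covs1,covs2 covariate names of the nested models.
#' @param n_boot number of bootstrap resamples (default 100; 0 skips the SE).
#' @return list: `delta`, `se`, `c1`, `c2` (`concordance_result`s),
#'   `boot_deltas`.
#' @export
delta_c <- function(data, covs1, covs2, n_boot = 100L) {
  fit1 <- fit_cox(data, covs1)
  fit2 <- fit_cox(data, covs2)
  c1 <- harrell_c(data$X, data$event, predict(fit1, data))
  c2 <- harrell_c(data$X, data$event, predict(fit2, data))
  boot <- delta_c_bootstrap(data, covs1, covs2, n_boot,
                            init1 = fit1$coef, init2 = fit2$coef)
  list(delta = c2$c - c1$c, se = boot$se, c1 = c1, c2 = c2,
       boot_deltas = boot$deltas)
}

#' Net reclassification improvement
#'
#' Classifies both probability vectors into the risk categories defined by
#' `cutpoints` and computes
#' `[P(up | event) - P(down | event)] - [P(up | non-event) - P(down | non-event)]`.
#' The SE treats the event and non-event groups as independent, with the
#' multinomial variance of the net proportion within each group.
#'
#' @param p1,p2 predicted event probabilities without / with the new
#'   variable.
#' @param events 0/1 event status.
#' @param cutpoints increasing interior cut-points on the probability scale.
#' @return list: `estimate`, `se`, per-group up/down counts.
#' @export
nri <- function(p1, p2, events, cutpoints = c(0.025, 0.05)) {
  stopifnot(length(p1) == length(p2), length(p1) == length(events))
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1))
    stop("probabilities must be in [0, 1]")
  if (length(cutpoints) < 1) stop("at least one cut-point (2 categories)")
  br <- c(-Inf, sort(cutpoints), Inf)
  k1 <- findInterval(p1, br)
  k2 <- findInterval(p2, br)
  e <- events == 1
  if (!any(e) || all(e)) stop("both events and non-events are required")
  net <- function(g) {
    up <- mean(k2[g] > k1[g]); down <- mean(k2[g] < k1[g])
    list(net = up - down,
         var = (up + down - (up - down)^2) / sum(g),
         n_up = sum(k2[g] > k1[g]), n_down = sum(k2[g] < k1[g]))
  }
  ev <- net(e); ne <- net(!e)
  list(estimate = ev$net - ne$net, se = sqrt(ev$var + ne$var),
       events_up = ev$n_up, events_down = ev$n_down,
       nonevents_up = ne$n_up, nonevents_down = ne$n_down,
       cutpoints = sort(cutpoints))
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slopes: the mean change in predicted
#' probability (`p2 - p1`) among events minus the mean change among
#' non-events.  SE combines the two groups' standard errors of the mean in
#' quadrature.
#'
#' @inheritParams nri
#' @return list: `estimate`, `se`.
#' @export
idi <- function(p1, p2, events) {
  stopifnot(length(p1) == length(p2), length(p1) == length(events))
  e <- events == 1
  if (!any(e) || all(e)) stop("both events and non-events are required")
  d <- p2 - p1
  est <- mean(d[e]) - mean(d[!e])
  se <- sqrt(var(d[e]) / sum(e) + var(d[!e]) / sum(!e))
  list(estimate = est, se = se)
}

pool_metric <- function(ests, vars) {
  pl <- pool_rubin(as.list(ests), as.list(vars))
  wt <- if (all(is.finite(vars))) wald_test(pl) else NULL
  list(estimate = unname(pl$theta), se = if (is.null(wt)) NA_real_ else wt$se,
       fmi = unname(pl$fmi), df = unname(pl$df),
       p_value = if (is.null(wt)) NA_real_ else wt$p_value,
       reject = if (is.null(wt)) NA else wt$reject,
       per_imputation = ests)
}

#' Predictive ability of a phase-2 variable by multiple imputation
#'
#' Reconstructs `M` plausible whole cohorts by proper imputation, computes
#' `C1`, `C2`, `delta = C2 - C1`, NRI and IDI on each completed cohort
#' (analytic variances for C, NRI and IDI; nonparametric bootstrap for the
#' within-imputation variance of `delta`), and pools everything by Rubin's
#' rules.
#'
#' @param case_cohort a case-cohort cohort table (masked phase-2 values).
#' @param spec an [imputation_spec()].
#' @param covs1 phase-1 covariates (model without the phase-2 variable).
#' @param covs2 covariates including the phase-2 variable.
#' @param horizon prediction horizon for the risk probabilities used by NRI
#'   and IDI (typically the end of follow-up).
#' @param M number of imputations.
#' @param n_boot bootstrap resamples per completed cohort for the SE of
#'   `delta` (default 100; 0 skips variance and tests for `delta`).
#' @param cutpoints NRI risk-category cut-points.
#' @param compute_nri set `FALSE` to skip NRI (no meaningful categories).
#' @return a `discrimination_result` with pooled `c1`, `c2`, `delta`,
#'   `nri`, `idi` (estimate, SE, fmi, test) plus `M` and `n_boot`.
#' @export
mi_discrimination <- function(case_cohort, spec, covs1, covs2, horizon,
                              M = spec$M, n_boot = 100L,
                              cutpoints = c(0.025, 0.05), compute_nri = TRUE) {
  impfit <- fit_imputation_model(case_cohort, spec)
  imps <- draw_imputations(case_cohort, impfit, M)
  per <- lapply(imps, single_discrimination, covs1 = covs1, covs2 = covs2,
                horizon = horizon, n_boot = n_boot, cutpoints = cutpoints,
                compute_nri = compute_nri)
  g <- function(f) vapply(per, f, numeric(1))
  out <- list(
    c1 = pool_metric(g(function(x) x$c1$c), g(function(x) x$c1$se^2)),
    c2 = pool_metric(g(function(x) x$c2$c), g(function(x) x$c2$se^2)),
    delta = pool_metric(g(function(x) x$delta), g(function(x) x$delta_se^2)),
    nri = if (compute_nri)
      pool_metric(g(function(x) x$nri$estimate), g(function(x) x$nri$se^2))
      else NULL,
    idi = pool_metric(g(function(x) x$idi$estimate), g(function(x) x$idi$se^2)),
    M = M, n_boot = n_boot, method = "mi", horizon = horizon,
    cutpoints = cutpoints)
  class(out) <- "discrimination_result"
  out
}

#' Naive predictive ability on the case-cohort subsample
#'
#' Computes the same metrics directly on the completely observed subjects
#' (cases plus subcohort), ignoring the design.  This estimator is biased
#' -- it underestimates C increasingly as the subcohort shrinks -- and is
#' provided to document the bias that imputation avoids.
#'
#' @inheritParams mi_discrimination
#' @return a `discrimination_result` (single data set, no pooling).
#' @export
naive_discrimination <- function(case_cohort, covs1, covs2, horizon,
                                 n_boot = 100L, cutpoints = c(0.025, 0.05),
                                 compute_nri = TRUE) {
  sub <- case_cohort[case_cohort$z2_observed == 1L, , drop = FALSE]
  full_discrimination(sub, covs1, covs2, horizon, n_boot = n_boot,
                      cutpoints = cutpoints, compute_nri = compute_nri,
                      method = "naive")
}

#' Predictive ability on a completely observed cohort
#'
#' Single-data-set version of [mi_discrimination()] for a fully observed
#' cohort: analytic SEs for C, NRI, IDI and a subject bootstrap for
#' `delta`, with normal-reference Wald tests.
#'
#' @inheritParams mi_discrimination
#' @param data a complete data set.
#' @param method label stored on the result.
#' @return a `discrimination_result`.
#' @export
full_discrimination <- function(data, covs1, covs2, horizon, n_boot = 100L,
                                cutpoints = c(0.025, 0.05), compute_nri = TRUE,
                                method = "full") {
  r <- single_discrimination(data, covs1, covs2, horizon, n_boot = n_boot,
                             cutpoints = cutpoints, compute_nri = compute_nri)
  ztest <- function(est, se) {
    if (!is.finite(se) || se <= 0)
      return(list(p_value = NA_real_, reject = NA))
    p <- 2 * pnorm(-abs(est / se))
    list(p_value = p, reject = p < 0.05)
  }
  wrap <- function(est, se) c(list(estimate = est, se = se), ztest(est, se))
  out <- list(
    c1 = wrap(r$c1$c, r$c1$se),
    c2 = wrap(r$c2$c, r$c2$se),
    delta = wrap(r$delta, r$delta_se),
    nri = if (compute_nri) wrap(r$nri$estimate, r$nri$se) else NULL,
    idi = wrap(r$idi$estimate, r$idi$se),
    M = 1L, n_boot = n_boot, method = method, horizon = horizon,
    cutpoints = cutpoints)
  class(out) <- "discrimination_result"
  out
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("Predictive ability (%s%s)\n", x$method,
              if (x$method == "mi") sprintf(", M = %d", x$M) else ""))
  rows <- c("c1", "c2", "delta", "nri", "idi")
  for (r in rows) {
    m <- x[[r]]
    if (is.null(m)) next
    cat(sprintf("  %-5s %8.4f  (SE %s%s)\n", toupper(r), m$estimate,
                ifelse(is.na(m$se), "NA", sprintf("%.4f", m$se)),
                if (!is.null(m$p_value) && !is.na(m$p_value))
                  sprintf(", p = %.3g", m$p_value) else ""))
  }
  invisible(x)
}
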