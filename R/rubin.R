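# Rubin's rules: pooling point estimates and variances across imputations

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the
#' total variance is the mean within-imputation variance plus
#' `(1 + 1/M)` times the between-imputation (co)variance, the `1 + 1/M`
#' factor adjusting for the finite number of imputations.  Per component
#' the fraction of missing information is `(1 + 1/M) B / total`, and the
#' small-sample degrees of freedom are `(M - 1) (1 + 1/r)^2` with
#' `r = (1 + 1/M) B / W` (infinite when `B = 0`).
#'
#' @param estimates list of length `M` of (equal-length, possibly named)
#'   numeric vectors, or a numeric vector of scalars.
#' @param variances list of length `M` of covariance matrices (or scalar
#'   variances), conformable with the estimates.
#' @return a `pooled_estimate`: `theta` (pooled vector), `W`, `B` (full
#'   between covariance), `total_var`, per-component `se`, `fmi`, `df`,
#'   and `M`.
#' @export
#' @examples
#' pool_rubin(list(1, 2, 3), list(0.1, 0.1, 0.1))
pool_rubin <- function(estimates, variances) {
  if (is.numeric(estimates)) estimates <- as.list(estimates)
  if (is.numeric(variances)) variances <- as.list(variances)
  M <- length(estimates)
  if (M < 2) stop("at least M = 2 imputations are required")
  if (length(variances) != M)
    stop("`estimates` and `variances` must have the same length")
  est <- do.call(rbind, lapply(estimates, function(e) as.numeric(e)))
  p <- ncol(est)
  nm <- names(estimates[[1]])
  vars <- lapply(variances, function(v) {
    v <- as.matrix(v)
    if (nrow(v) != ncol(v)) stop("variance inputs must be square")
    if (nrow(v) == 1 && p > 1 || nrow(v) != p)
      stop("variance dimension does not match estimates")
    v
  })
  theta <- colMeans(est)
  W <- Reduce(`+`, vars) / M
  B <- cov(est)                                  # divisor M - 1
  Tm <- W + (1 + 1 / M) * B
  Wd <- diag(as.matrix(W)); Bd <- diag(as.matrix(B)); Td <- diag(as.matrix(Tm))
  fmi <- ifelse(Td > 0, (1 + 1 / M) * Bd / Td, 0)
  r <- ifelse(Wd > 0, (1 + 1 / M) * Bd / Wd, Inf)
  df <- ifelse(r > 0, (M - 1) * (1 + 1 / r)^2, Inf)
  names(theta) <- nm
  out <- list(theta = theta, W = W, B = B, total_var = Tm,
              se = sqrt(Td), fmi = fmi, df = df, M = M)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Rubin-pooled estimate over M = %d imputations\n", x$M))
  tab <- data.frame(estimate = x$theta, se = x$se, fmi = x$fmi, df = x$df)
  print(round(tab, 4))
  invisible(x)
}

#' Wald test of a pooled component
#'
#' t statistic `(theta - null) / sqrt(total_var)` referred to Student's t
#' with Rubin's small-sample degrees of freedom (normal reference when the
#' between-imputation variance is zero, `df = Inf`).
#'
#' @param pooled a `pooled_estimate`.
#' @param null null value (default 0).
#' @param component index or name of the component to test.
#' @param alpha significance level for the `reject` flag.
#' @return list: `statistic`, `df`, `p_value`, `reject`, `estimate`, `se`.
#' @export
wald_test <- function(pooled, null = 0, component = 1L, alpha = 0.05) {
  stopifnot(inherits(pooled, "pooled_estimate"))
  th <- pooled$theta[component]
  v <- diag(as.matrix(pooled$total_var))[component]
  df <- pooled$df[component]
  if (v <= 0) {
    if (abs(th - null) > 0) stop("zero total variance with estimate != null")
    return(list(statistic = 0, df = df, p_value = 1, reject = FALSE,
                estimate = unname(th), se = 0))
  }
  stat <- (th - null) / sqrt(v)
  p <- if (is.finite(df)) 2 * pt(-abs(stat), df) else 2 * pnorm(-abs(stat))
  list(statistic = unname(stat), df = unname(df), p_value = unname(p),
       reject = unname(p < alpha), estimate = unname(th),
       se = unname(sqrt(v)))
}

#' JSON-friendly summary of a pooled estimate
#'
#' @param pooled a `pooled_estimate`.
#' @param level confidence level (t reference with Rubin df).
#' @return list of per-component estimate, SE, CI, fmi and df.
#' @export
pooled_summary <- function(pooled, level = 0.95) {
  tq <- ifelse(is.finite(pooled$df),
               qt(1 - (1 - level) / 2, pooled$df),
               qnorm(1 - (1 - level) / 2))
  list(estimate = unname(pooled$theta), se = unname(pooled$se),
       ci_lower = unname(pooled$theta - tq * pooled$se),
       ci_upper = unname(pooled$theta + tq * pooled$se),
       fmi = unname(pooled$fmi), df = unname(pooled$df), M = pooled$M)
}
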