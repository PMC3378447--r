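# mi engine: imputation model on complete records, proper multiple draws

#' Specify the imputation model for the phase-2 variable
#'
#' The model regresses the phase-2 variable on the case indicator (always
#' included -- under the rare-disease assumption the case status carries
#' the outcome information) and, with stratified subcohort sampling, the
#' stratum indicators; further covariates or surrogates can be added.  The
#' `stratum` predictor is expanded into indicator variables.
#'
#' @param target name of the (possibly missing) phase-2 column.
#' @param predictors character vector of predictor columns; must include
#'   `"event"` (the case indicator); `"stratum"` is treated as categorical.
#' @param family `"gaussian"` (normal linear model) or `"categorical"`
#'   (multinomial logistic for a factor/integer-coded target).
#' @param M default number of imputations (>= 2).
#' @return an `imputation_spec`.
#' @export
imputation_spec <- function(target = "Z2",
                            predictors = c("event", "stratum"),
                            family = c("gaussian", "categorical"),
                            M = 5L) {
  family <- match.arg(family)
  if (!"event" %in% predictors)
    stop("the case indicator `event` must be among the predictors")
  if (target %in% predictors)
    stop("`target` cannot be one of its own predictors")
  if (M < 2) stop("`M` must be at least 2")
  out <- list(target = target, predictors = predictors, family = family,
              M = as.integer(M))
  class(out) <- "imputation_spec"
  out
}

imputation_formula <- function(spec) {
  rhs <- vapply(spec$predictors, function(v)
    if (v == "stratum") "factor(stratum)" else v, character(1))
  as.formula(paste("~", paste(rhs, collapse = " + ")))
}

# multinomial logistic log-likelihood for K categories, theta is the
# (K-1) x p coefficient matrix flattened row-wise; category 1 is reference
multinom_loglik <- function(theta, X, y, K) {
  p <- ncol(X)
  Th <- matrix(theta, nrow = K - 1, ncol = p, byrow = TRUE)
  eta <- X %*% t(Th)                       # n x (K-1)
  m <- pmax(apply(eta, 1, max), 0)
  logden <- m + log(exp(-m) + rowSums(exp(eta - m)))
  ll <- -sum(logden)
  idx <- y > 1L
  ll + sum(eta[cbind(which(idx), y[idx] - 1L)])
}

#' Fit the imputation model on completely observed subjects
#'
#' Ordinary least squares (gaussian family) or multinomial logistic
#' (categorical family) on the records with `z2_observed == 1`.  Both cases
#' and non-cases must be present among the complete records.
#'
#' @param data a case-cohort cohort table.
#' @param spec an [imputation_spec()].
#' @return an `imputation_fit`: coefficient estimates, their (scaled)
#'   covariance, residual variance and degrees of freedom (gaussian) or the
#'   coefficient matrix with its asymptotic covariance (categorical), and
#'   `n_complete`.  A gaussian fit with (numerically) zero residual
#'   variance is flagged `degenerate`.
#' @export
fit_imputation_model <- function(data, spec) {
  stopifnot(inherits(spec, "imputation_spec"))
  obs <- data$z2_observed == 1L
  comp <- data[obs, , drop = FALSE]
  f <- imputation_formula(spec)
  X <- model.matrix(f, comp)
  y <- comp[[spec$target]]
  if (anyNA(y)) stop("target has missing values among complete records")
  p <- ncol(X)
  if (nrow(X) < p + 2)
    stop("too few complete records (", nrow(X), ") for ", p, " parameters")
  if (length(unique(comp$event)) < 2)
    stop("complete records must contain both cases and non-cases")

  if (spec$family == "gaussian") {
    qrX <- qr(X)
    if (qrX$rank < p) stop("rank-deficient imputation design matrix")
    coefs <- qr.coef(qrX, y)
    fitted <- drop(X %*% coefs)
    rss <- sum((y - fitted)^2)
    df <- nrow(X) - p
    sigma2 <- rss / df
    R <- qr.R(qrX)
    XtX_inv <- chol2inv(R)
    dimnames(XtX_inv) <- list(colnames(X), colnames(X))
    out <- list(family = "gaussian", spec = spec, coef = coefs,
                XtX_inv = XtX_inv, rss = rss, df = df,
                sigma2_resid = sigma2,
                degenerate = sigma2 < 1e-12 * max(1, mean(y^2)),
                n_complete = nrow(X))
  } else {
    yf <- factor(y)
    K <- nlevels(yf)
    if (K < 2) stop("categorical target needs at least 2 observed categories")
    yi <- as.integer(yf)
    th0 <- rep(0, (K - 1) * p)
    opt <- optim(th0, multinom_loglik, X = X, y = yi, K = K,
                 method = "BFGS",
                 control = list(fnscale = -1, maxit = 500, reltol = 1e-12),
                 hessian = TRUE)
    if (opt$convergence != 0)
      warning("multinomial imputation model did not fully converge")
    V <- tryCatch(solve(-opt$hessian), error = function(e)
      stop("singular information in categorical imputation model ",
           "(a category may be nearly unobserved)"))
    ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
    unstable <- any(ev > 100) || min(table(yi)) < 5
    if (unstable)
      warning("categorical imputation model may be unstable: small ",
              "category counts, asymptotic draws can be unreliable")
    out <- list(family = "categorical", spec = spec,
                coef = matrix(opt$par, nrow = K - 1, ncol = p, byrow = TRUE,
                              dimnames = list(levels(yf)[-1], colnames(X))),
                vcov = V, levels = levels(yf),
                target_factor = is.factor(data[[spec$target]]),
                loglik = opt$value, unstable = unstable,
                n_complete = nrow(X))
  }
  class(out) <- "imputation_fit"
  out
}

#' @export
print.imputation_fit <- function(x, ...) {
  cat(sprintf("Imputation model (%s) for `%s` on %d complete records\n",
              x$family, x$spec$target, x$n_complete))
  if (x$family == "gaussian") {
    print(round(x$coef, 4))
    cat(sprintf("residual variance = %.5f on %d df%s\n", x$sigma2_resid,
                x$df, if (x$degenerate) " [degenerate]" else ""))
  } else {
    print(round(x$coef, 4))
  }
  invisible(x)
}

#' Generate M properly imputed completed cohorts
#'
#' Proper multiple imputation under the noninformative-prior normal linear
#' scheme: for each imputation, the residual variance is drawn from its
#' scaled inverse-chi-square sampling distribution, the coefficients from
#' their normal distribution given that draw, and each missing value from
#' the resulting predictive normal.  For the categorical family the
#' coefficients are drawn from the asymptotic normal of the multinomial
#' MLE and missing categories from the implied probabilities.  Observed
#' values are never altered.  A degenerate gaussian fit (zero residual
#' variance) imputes the fitted means exactly.
#'
#' @param data the case-cohort cohort table (with masked values).
#' @param fit an `imputation_fit`.
#' @param M number of completed data sets (>= 2); defaults to the spec's M.
#' @return list of `M` completed cohort tables.
#' @export
draw_imputations <- function(data, fit, M = fit$spec$M) {
  stopifnot(inherits(fit, "imputation_fit"))
  if (M < 2) stop("`M` must be at least 2")
  spec <- fit$spec
  misrows <- which(data$z2_observed == 0L)
  out <- vector("list", M)
  if (length(misrows) == 0) {
    for (m in seq_len(M)) out[[m]] <- data
    return(out)
  }
  f <- imputation_formula(spec)
  # build the design on the full table so factor levels match the fit
  Xm <- model.matrix(f, data)[misrows, , drop = FALSE]
  fit_cols <- if (fit$family == "gaussian") names(fit$coef) else colnames(fit$coef)
  if (!identical(colnames(Xm), fit_cols))
    stop("rows needing imputation use predictor levels absent from the fit")
  nm <- length(misrows)
  for (m in seq_len(M)) {
    d <- data
    if (fit$family == "gaussian") {
      if (fit$degenerate) {
        imp <- drop(Xm %*% fit$coef)
      } else {
        sig2 <- fit$rss / rchisq(1, fit$df)
        R <- chol(fit$XtX_inv)
        alpha <- fit$coef + sqrt(sig2) * drop(t(R) %*% rnorm(length(fit$coef)))
        imp <- drop(Xm %*% alpha) + rnorm(nm, 0, sqrt(sig2))
      }
      d[[spec$target]][misrows] <- imp
    } else {
      p <- ncol(fit$coef); K <- length(fit$levels)
      R <- chol(fit$vcov)
      th <- as.vector(t(fit$coef)) + drop(t(R) %*% rnorm((K - 1) * p))
      Th <- matrix(th, nrow = K - 1, ncol = p, byrow = TRUE)
      eta <- cbind(0, Xm %*% t(Th))
      pr <- exp(eta - apply(eta, 1, max))
      pr <- pr / rowSums(pr)
      ki <- vapply(seq_len(nm), function(i)
        sample.int(K, 1L, prob = pr[i, ]), integer(1))
      val <- fit$levels[ki]
      d[[spec$target]][misrows] <-
        if (fit$target_factor) factor(val, levels = fit$levels)
        else if (is.numeric(data[[spec$target]])) as.numeric(val) else val
    }
    out[[m]] <- d
  }
  out
}
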