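# cohort simulator and stratified case-cohort sampler

# quantile-group labels 1..k computed on the realized vector, ties broken
# by first-occurrence rank so the groups always partition the cohort
quantile_group <- function(x, k) {
  n <- length(x)
  as.integer(ceiling(k * rank(x, ties.method = "first") / n))
}

#' Simulate a full cohort
#'
#' Generates a cohort under the scenario's exponential proportional-hazards
#' mechanism.  `Z2` is drawn with the configured marginal (standardized to
#' unit variance), correlated `rho23` with `Z3` through a Gaussian copula,
#' and independent of `Z1`.  Survival times are exponential with rate
#' `exp(beta1*Z1 + beta2*Z2 + beta3*Z3)`, censoring is uniform on
#' `(0, tau)`, and the stratum label crosses quantile groups of the
#' surrogate `Z2_surr = Z2 + eps` and of `Z3`, both computed on the full
#' cohort (phase-1 information only).
#'
#' @param config a [scenario_config()].
#' @return A `data.frame` ("cohort table") with one row per subject:
#'   `id`, `Z1`, `Z2`, `Z3`, `Z2_surr`, `X` (observed time), `event`,
#'   `stratum`, `in_subcohort` (0 until [draw_case_cohort()] is applied) and
#'   `z2_observed` (1 for a freshly simulated full cohort).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$N
  Z1 <- rbinom(n, 1L, 0.5)
  G <- rnorm(n)                     # latent normal behind Z2
  r <- config$latent_rho
  Z3 <- r * G + sqrt(1 - r^2) * rnorm(n)
  Z2 <- switch(config$z2_dist,
               normal    = G,
               lognormal = (exp(G) - exp(0.5)) / sqrt(exp(2) - exp(1)),
               uniform   = sqrt(12) * (pnorm(G) - 0.5))
  lambda <- exp(config$beta1 * Z1 + config$beta2 * Z2 + config$beta3 * Z3)
  T_lat <- rexp(n, rate = lambda)
  C_lat <- runif(n, 0, config$tau)
  X <- pmin(T_lat, C_lat)
  event <- as.integer(T_lat <= C_lat)
  Z2_surr <- Z2 + rnorm(n, 0, sqrt(config$sigma2_surr))
  k <- config$n_strata_per_axis
  stratum <- as.integer(k * (quantile_group(Z2_surr, k) - 1L) +
                          quantile_group(Z3, k))
  out <- data.frame(id = seq_len(n), Z1 = Z1, Z2 = Z2, Z3 = Z3,
                    Z2_surr = Z2_surr, X = X, event = event,
                    stratum = stratum, in_subcohort = 0L,
                    z2_observed = 1L)
  class(out) <- c("cohort_table", "data.frame")
  out
}

# proportional allocation with largest-remainder rounding
proportional_allocation <- function(stratum_sizes, total) {
  target <- total * stratum_sizes / sum(stratum_sizes)
  alloc <- floor(target)
  rem <- total - sum(alloc)
  if (rem > 0) {
    frac <- target - alloc
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    alloc[bump] <- alloc[bump] + 1
  }
  if (any(alloc > stratum_sizes))
    stop("stratum allocation exceeds stratum size")
  as.integer(alloc)
}

#' Draw a stratified case-cohort sample
#'
#' Selects a subcohort by stratified simple random sampling (allocated
#' proportionally to stratum sizes, largest-remainder rounding), sampled
#' from the whole cohort so that cases may fall in it, then masks the
#' phase-2 covariate of every non-case outside the subcohort
#' (`z2_observed = 0`, `Z2 = NA`).  Cases always keep their `Z2`.
#'
#' @param cohort a cohort table from [simulate_cohort()] (or read by
#'   [read_cohort()]) with `stratum` labels.
#' @param subcohort_size total subcohort size; defaults to the value stored
#'   in `config`.
#' @param config optional [scenario_config()] supplying `subcohort_size`.
#' @return The cohort table with `in_subcohort`, `z2_observed` and masked
#'   `Z2` updated; all other fields untouched.
#' @export
draw_case_cohort <- function(cohort, subcohort_size = NULL, config = NULL) {
  if (is.null(subcohort_size)) {
    if (is.null(config)) stop("supply `subcohort_size` or `config`")
    subcohort_size <- config$subcohort_size
  }
  n <- nrow(cohort)
  if (subcohort_size < 1 || subcohort_size > n)
    stop("`subcohort_size` must be in [1, nrow(cohort)]")
  if (anyNA(cohort$stratum)) stop("cohort must carry stratum labels")
  strata <- sort(unique(cohort$stratum))
  sizes <- vapply(strata, function(s) sum(cohort$stratum == s), integer(1))
  alloc <- proportional_allocation(sizes, subcohort_size)
  in_sub <- rep(0L, n)
  for (i in seq_along(strata)) {
    idx <- which(cohort$stratum == strata[i])
    if (alloc[i] > 0)
      in_sub[sample(idx, alloc[i])] <- 1L
  }
  cohort$in_subcohort <- in_sub
  cohort$z2_observed <- as.integer(cohort$event == 1L | in_sub == 1L)
  cohort$Z2[cohort$z2_observed == 0L] <- NA_real_
  cohort
}

#' Read or write a cohort table as CSV
#'
#' Missing phase-2 values are encoded as empty fields.
#'
#' @param cohort a cohort table.
#' @param path file path.
#' @return `read_cohort()` returns the cohort table; `write_cohort()`
#'   returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- read.csv(path, na.strings = "")
  needed <- c("X", "event")
  miss <- setdiff(needed, names(out))
  if (length(miss))
    stop("cohort file lacks required columns: ", paste(miss, collapse = ", "))
  if (!"z2_observed" %in% names(out) && "Z2" %in% names(out))
    out$z2_observed <- as.integer(!is.na(out$Z2))
  if (!"in_subcohort" %in% names(out)) out$in_subcohort <- 0L
  class(out) <- c("cohort_table", "data.frame")
  out
}
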