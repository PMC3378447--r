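# independent oracles used across the suite (deliberately brute-force /
# written out, never calling the package's fast paths)

# written-out Cox partial log-likelihood (Breslow), any weights
pl_loglik_oracle <- function(beta, time, status, X, w = rep(1, length(time))) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in seq_along(time)) {
    if (status[i] != 1) next
    rs <- time >= time[i]
    ll <- ll + w[i] * (eta[i] - log(sum(w[rs] * exp(eta[rs]))))
  }
  ll
}

# brute-force maximizer of the written-out partial likelihood
pl_maximize_oracle <- function(time, status, X, w = rep(1, length(time))) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p == 1) {
    opt <- optimize(function(b) pl_loglik_oracle(b, time, status, X, w),
                    interval = c(-20, 20), maximum = TRUE, tol = 1e-10)
    opt$maximum
  } else {
    opt <- optim(rep(0, p), pl_loglik_oracle, time = time, status = status,
                 X = X, w = w, method = "BFGS",
                 control = list(fnscale = -1, reltol = 1e-14, maxit = 1000))
    opt$par
  }
}

# exhaustive O(n^2) usable-pair enumeration for Harrell's C
concordance_oracle <- function(time, status, score) {
  conc <- 0; usable <- 0
  n <- length(time)
  for (i in seq_len(n)) {
    if (status[i] != 1) next
    for (j in seq_len(n)) {
      if (j == i) next
      use <- if (status[j] == 1) time[j] > time[i] else time[j] >= time[i]
      if (!use) next
      usable <- usable + 1
      conc <- conc +
        if (score[i] > score[j]) 1 else if (score[i] == score[j]) 0.5 else 0
    }
  }
  list(c = conc / usable, concordant = conc, usable = usable)
}

# six-subject toy data used by several Cox tests
toy6 <- function() {
  data.frame(id = 1:6, X = c(1, 2, 3, 4, 5, 6),
             event = c(1L, 1L, 0L, 1L, 0L, 0L),
             Z = c(1, 0, 1, 0, 1, 0))
}

# small simulated cohort for unit tests (kept small for speed)
small_cohort <- function(n = 2000, seed = 42, ...) {
  simulate_cohort(scenario_config(N = n, seed = seed,
                                  subcohort_size = min(1000, max(2, n %/% 5)),
                                  ...))
}

# random survival instance with optional ties, for property tests
random_instance <- function(n, seed, tie_prob = 0.3) {
  set.seed(seed)
  time <- if (runif(1) < tie_prob) sample(1:max(2, n %/% 2), n, replace = TRUE)
          else rexp(n)
  status <- rbinom(n, 1, 0.6)
  if (all(status == 0)) status[1] <- 1L
  score <- if (runif(1) < tie_prob) sample(1:3, n, replace = TRUE)
           else rnorm(n)
  list(time = time, status = status, score = score)
}
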