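# proportional-hazards engine vs brute-force and survival::coxph oracles

test_that("toy fit matches the brute-force partial-likelihood maximizer", {
  d <- toy6()
  fit <- fit_cox(d, "Z")
  b_oracle <- pl_maximize_oracle(d$X, d$event, d$Z)
  expect_equal(unname(coef(fit)), b_oracle, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_events, 3)
})

test_that("random small instances match 1-D/2-D brute force", {
  for (s in 1:12) {
    set.seed(100 + s)
    n <- sample(4:8, 1)
    p <- sample(1:2, 1)
    d <- data.frame(X = round(rexp(n), 2) + 0.01,
                    event = rbinom(n, 1, 0.7))
    if (sum(d$event) == 0) d$event[1] <- 1L
    X <- matrix(rnorm(n * p), n, p)
    d$V1 <- X[, 1]
    covs <- "V1"
    if (p == 2) { d$V2 <- X[, 2]; covs <- c("V1", "V2") }
    fit <- suppressWarnings(fit_cox(d, covs))
    # skip (near-)separated instances: the likelihood plateaus and both the
    # fit and the oracle stop at arbitrary points on the plateau
    if (!fit$converged || max(abs(coef(fit))) > 5) next
    b <- pl_maximize_oracle(d$X, d$event, X)
    expect_equal(unname(coef(fit)), unname(b), tolerance = 1e-4,
                 label = sprintf("seed %d", s))
    # weighted: integer weights equal replication of rows
    w <- sample(1:3, n, replace = TRUE)
    fw <- suppressWarnings(fit_cox(d, covs, weights = w))
    if (fw$converged && max(abs(coef(fw))) <= 5) {
      bw <- pl_maximize_oracle(d$X, d$event, X, w)
      expect_equal(unname(coef(fw)), unname(bw), tolerance = 1e-4)
    }
  }
})

test_that("all weights one is identical to the unweighted fit", {
  co <- small_cohort(1500, seed = 7)
  f1 <- fit_cox(co, c("Z1", "Z2", "Z3"))
  f2 <- fit_cox(co, c("Z1", "Z2", "Z3"), weights = rep(1, nrow(co)))
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$loglik, f2$loglik)
})

test_that("coefficients, covariances and baseline match survival::coxph", {
  skip_if_not_installed("survival")
  co <- small_cohort(3000, seed = 8)
  fit <- fit_cox(co, c("Z1", "Z2", "Z3"))
  ref <- survival::coxph(survival::Surv(X, event) ~ Z1 + Z2 + Z3,
                         data = co, ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$cov_model), unname(vcov(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
  bh <- survival::basehaz(ref, centered = FALSE)
  mine <- fit$baseline
  idx <- match(round(mine$time, 12), round(bh$time, 12))
  expect_equal(mine$cumhaz, bh$hazard[idx], tolerance = 1e-6)

  # weighted fit incl. robust sandwich
  set.seed(4)
  cc <- draw_case_cohort(co, 600)
  w <- borgan_weights(cc)
  fw <- fit_borgan(cc, c("Z1", "Z2", "Z3"))
  keep <- w > 0
  rw <- survival::coxph(survival::Surv(X, event) ~ Z1 + Z2 + Z3,
                        data = cc[keep, ], weights = w[keep],
                        ties = "breslow", robust = TRUE)
  expect_equal(unname(coef(fw)), unname(coef(rw)), tolerance = 1e-5)
  expect_equal(unname(sqrt(diag(fw$cov_robust))),
               unname(sqrt(diag(vcov(rw)))), tolerance = 1e-5)
})

test_that("delayed entry reproduces coxph start-stop fits", {
  skip_if_not_installed("survival")
  co <- small_cohort(2000, seed = 9)
  set.seed(5)
  entry <- runif(nrow(co), 0, co$X * 0.9)
  fit <- fit_cox(co, c("Z1", "Z3"), entry = entry)
  ref <- survival::coxph(survival::Surv(entry, X, event) ~ Z1 + Z3,
                         data = cbind(co, entry = entry), ties = "breslow")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("errors and warnings are raised as specified", {
  co <- small_cohort(500, seed = 10)
  co0 <- co; co0$event <- 0L
  expect_error(fit_cox(co0, "Z1"), "at least one event")
  expect_error(fit_cox(co, "nope"), "unknown covariates")
  expect_error(fit_cox(co, "Z1", weights = rep(-1, nrow(co))), "non-negative")
  com <- co; com$Z2[1] <- NA
  expect_error(fit_cox(com, "Z2"), "missing covariate")
  # complete separation is reported, not silent
  ds <- data.frame(X = c(1, 2, 3, 4), event = c(1L, 1L, 0L, 0L),
                   Z = c(5, 4, 0, 0))
  expect_warning(fit_cox(ds, "Z"), "separation|did not converge")
})

test_that("borgan weights follow the stratified inverse sampling fractions", {
  # constructed table: one stratum with 990 non-cases, 99 sampled -> 10
  d <- data.frame(event = c(rep(1L, 10), rep(0L, 990)),
                  in_subcohort = c(rep(0L, 10), rep(1L, 99), rep(0L, 891)),
                  stratum = 1L)
  w <- borgan_weights(d)
  expect_true(all(w[d$event == 1] == 1))
  expect_true(all(w[d$event == 0 & d$in_subcohort == 1] == 10))
  expect_true(all(w[d$event == 0 & d$in_subcohort == 0] == 0))
  # telescoping: non-case weights in each stratum sum to cohort non-cases
  co <- small_cohort(4000, seed = 12)
  set.seed(6)
  cc <- draw_case_cohort(co, 800)
  w <- borgan_weights(cc)
  for (s in unique(cc$stratum)) {
    nc <- cc$event == 0 & cc$stratum == s
    expect_equal(sum(w[nc]), sum(nc))
  }
  # empty sampled stratum is an error
  bad <- data.frame(event = c(1L, 0L, 0L), in_subcohort = c(0L, 0L, 0L),
                    stratum = c(1L, 1L, 1L))
  expect_error(borgan_weights(bad), "no sampled non-cases")
})

test_that("predicted risk uses the Breslow baseline correctly", {
  d <- toy6()
  fit <- fit_cox(d, "Z")
  b <- unname(coef(fit))
  # hand-computed Breslow increments: at each event time, 1 / sum of
  # exp(b z) over subjects still at risk
  risk <- exp(b * d$Z)
  inc <- vapply(d$X[d$event == 1], function(t) 1 / sum(risk[d$X >= t]),
                numeric(1))
  expect_equal(fit$baseline$hazard, inc, tolerance = 1e-10)
  # predicted probabilities from the hand baseline
  for (h in c(2.5, 6)) {
    L0 <- sum(inc[d$X[d$event == 1] <= h])
    expect_equal(predicted_risk(fit, d, h), 1 - exp(-L0 * risk),
                 tolerance = 1e-10)
  }
  # zero coefficients give identical risk for everyone
  co <- small_cohort(800, seed = 13)
  f0 <- fit_cox(co, c("Z1", "Z2", "Z3"))
  f0$coef[] <- 0
  expect_equal(length(unique(predicted_risk(f0, co, 0.01))), 1L)
  # monotone in the linear predictor
  f <- fit_cox(co, c("Z1", "Z2", "Z3"))
  lp <- predict(f, co)
  pr <- predicted_risk(f, co, 0.02)
  expect_equal(order(lp), order(pr))
  expect_true(all(pr >= 0 & pr <= 1))
  expect_error(predicted_risk(f, co, -1), "positive")
})

test_that("the at-failure Borgan variant runs and tracks the default", {
  co <- small_cohort(6000, seed = 14)
  set.seed(7)
  cc <- draw_case_cohort(co, 1200)
  f_full <- fit_borgan(cc, c("Z1", "Z2", "Z3"), case_entry = "full")
  f_fail <- fit_borgan(cc, c("Z1", "Z2", "Z3"), case_entry = "at_failure")
  expect_true(f_fail$converged)
  expect_lt(max(abs(coef(f_fail) - coef(f_full))), 0.25)
})
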