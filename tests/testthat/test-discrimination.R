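# Harrell's C (usable-pair rule), delta C, NRI, IDI, and MI pooling

test_that("four-subject worked example gives C = 4/5", {
  res <- harrell_c(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1),
                   score = c(0.9, 0.7, 0.5, 0.8))
  expect_equal(res$n_usable, 5)
  expect_equal(res$n_concordant, 4)
  expect_equal(res$c, 4 / 5)
})

test_that("perfect ranking gives C = 1; null scores give C near 0.5", {
  set.seed(30)
  t <- sort(rexp(60)); s <- rev(seq_along(t))   # higher score, earlier event
  expect_equal(harrell_c(t, rep(1, 60), s)$c, 1)
  n <- 5000
  tim <- rexp(n); ev <- rbinom(n, 1, 0.5); sc <- rnorm(n)
  expect_lt(abs(harrell_c(tim, ev, sc)$c - 0.5), 0.02)
})

test_that("fast and exhaustive paths agree exactly with the pair oracle", {
  for (s in 1:25) {
    inst <- random_instance(n = sample(10:50, 1), seed = 300 + s)
    orc <- concordance_oracle(inst$time, inst$status, inst$score)
    slow <- harrell_c(inst$time, inst$status, inst$score)
    fast <- harrell_c(inst$time, inst$status, inst$score, variance = FALSE)
    expect_identical(slow$c, orc$c, label = sprintf("slow, seed %d", s))
    expect_identical(slow$n_usable, orc$usable)
    expect_identical(slow$n_concordant, orc$concordant)
    expect_identical(fast$c, orc$c, label = sprintf("fast, seed %d", s))
    expect_identical(fast$n_usable, orc$usable)
  }
})

test_that("C(scores) + C(-scores) = 1 on tie-free data", {
  set.seed(31)
  n <- 400
  tim <- rexp(n); ev <- rbinom(n, 1, 0.4); sc <- rnorm(n)
  expect_equal(harrell_c(tim, ev, sc)$c + harrell_c(tim, ev, -sc)$c, 1)
})

test_that("agreement with survival::concordance on tie-free data", {
  skip_if_not_installed("survival")
  co <- small_cohort(2500, seed = 32)
  s <- co$Z2 + 0.5 * co$Z3
  mine <- harrell_c(co$X, co$event, s)
  ref <- survival::concordance(survival::Surv(X, event) ~ s, data = co,
                               reverse = TRUE)
  expect_equal(mine$c, unname(ref$concordance), tolerance = 1e-12)
})

test_that("constant scores report 0.5 with a warning; errors as specified", {
  expect_warning(r <- harrell_c(c(1, 2, 3), c(1, 1, 0), c(2, 2, 2)),
                 "constant")
  expect_equal(r$c, 0.5)
  expect_error(harrell_c(c(1, 2), c(0, 0), c(1, 2)), "at least one event")
  expect_error(harrell_c(c(2, 1), c(0, 1), c(1, 2)), NA)
  expect_error(harrell_c(c(1, 1), c(1, 1), c(1, 2)), "no usable pairs")
})

test_that("jackknife and U-statistic SEs are of the same magnitude", {
  co <- small_cohort(1000, seed = 33)
  s <- co$Z2
  a <- harrell_c(co$X, co$event, s, se_method = "ustat")
  b <- harrell_c(co$X, co$event, s, se_method = "jackknife")
  expect_lt(abs(a$se / b$se - 1), 0.25)
})

test_that("identical models give delta exactly zero", {
  co <- small_cohort(800, seed = 34)
  set.seed(35)
  r <- delta_c(co, c("Z1", "Z3"), c("Z1", "Z3"), n_boot = 5)
  expect_identical(r$delta, 0)
  expect_equal(r$se, 0)
})

test_that("bootstrap delta SE is reproducible and positive", {
  co <- small_cohort(1200, seed = 36)
  set.seed(37)
  r1 <- delta_c(co, c("Z1", "Z3"), c("Z1", "Z2", "Z3"), n_boot = 30)
  set.seed(37)
  r2 <- delta_c(co, c("Z1", "Z3"), c("Z1", "Z2", "Z3"), n_boot = 30)
  expect_equal(r1$se, r2$se)
  expect_gt(r1$se, 0)
  expect_length(r1$boot_deltas, 30)
})

test_that("NRI toy counts: 4 events (2 up, 1 down), 10 non-events (1 up, 2 down)", {
  # construct category moves directly through probabilities
  cuts <- c(0.3, 0.6)
  ev <- c(1, 1, 1, 1, rep(0, 10))
  p1 <- c(0.1, 0.1, 0.7, 0.4, 0.1, 0.7, 0.7, rep(0.4, 7))
  p2 <- c(0.4, 0.7, 0.4, 0.4, 0.7, 0.4, 0.1, rep(0.4, 7))
  r <- nri(p1, p2, ev, cutpoints = cuts)
  expect_equal(r$estimate, (2 - 1) / 4 - (1 - 2) / 10)
  expect_equal(r$estimate, 0.35)
  expect_equal(r$events_up, 2); expect_equal(r$events_down, 1)
  expect_equal(r$nonevents_up, 1); expect_equal(r$nonevents_down, 2)
  # hand SE: multinomial net-move variance per group
  v_e <- (3 / 4 - (1 / 4)^2) / 4
  v_n <- (3 / 10 - (-1 / 10)^2) / 10
  expect_equal(r$se, sqrt(v_e + v_n))
})

test_that("IDI hand example and identities", {
  # events p-diffs (0.1, 0.3); non-events (0, 0, 0.1)
  ev <- c(1, 1, 0, 0, 0)
  p1 <- c(0.2, 0.2, 0.1, 0.1, 0.1)
  p2 <- p1 + c(0.1, 0.3, 0, 0, 0.1)
  r <- idi(p1, p2, ev)
  expect_equal(r$estimate, 0.2 - 0.1 / 3)
  expect_equal(r$se, sqrt(var(c(0.1, 0.3)) / 2 + var(c(0, 0, 0.1)) / 3))
  # p2 = p1: both metrics exactly zero
  expect_equal(nri(p1, p1, ev)$estimate, 0)
  expect_equal(idi(p1, p1, ev)$estimate, 0)
  expect_error(idi(p1, p2, rep(1, 5)), "both events and non-events")
  expect_error(nri(p1, p2, rep(0, 5)), "both events and non-events")
})

test_that("MI discrimination with no missing data equals the single-cohort
           computation with zero between-imputation variance", {
  co <- small_cohort(1500, seed = 38)
  co$z2_observed <- 1L   # nothing missing, draws are copies
  set.seed(39)
  single <- full_discrimination(co, c("Z1", "Z3"), c("Z1", "Z2", "Z3"),
                                horizon = 0.02, n_boot = 5)
  set.seed(39)
  mi <- mi_discrimination(co, imputation_spec(), c("Z1", "Z3"),
                          c("Z1", "Z2", "Z3"), horizon = 0.02, M = 3,
                          n_boot = 5)
  for (m in c("c1", "c2", "delta", "nri", "idi")) {
    expect_equal(mi[[m]]$estimate, single[[m]]$estimate,
                 tolerance = 1e-12, label = m)
    expect_equal(mi[[m]]$fmi, 0, label = m)
  }
})

test_that("pooled MI metrics are invariant to imputation order (seeded)", {
  co <- small_cohort(1200, seed = 40)
  set.seed(41)
  cc <- draw_case_cohort(co, 240)
  fit <- fit_imputation_model(cc, imputation_spec())
  set.seed(42)
  imps <- draw_imputations(cc, fit, M = 4)
  per <- lapply(imps, function(d) {
    f2 <- fit_cox(d, c("Z1", "Z2", "Z3"))
    harrell_c(d$X, d$event, predict(f2, d))
  })
  ests <- vapply(per, function(x) x$c, numeric(1))
  vars <- vapply(per, function(x) x$se^2, numeric(1))
  p1 <- pool_rubin(as.list(ests), as.list(vars))
  perm <- c(3, 1, 4, 2)
  p2 <- pool_rubin(as.list(ests[perm]), as.list(vars[perm]))
  expect_equal(p1$theta, p2$theta)
  expect_equal(p1$total_var, p2$total_var)
})

test_that("naive discrimination restricts to completely observed subjects", {
  co <- small_cohort(2500, seed = 43)
  set.seed(44)
  cc <- draw_case_cohort(co, 500)
  set.seed(45)
  r <- naive_discrimination(cc, c("Z1", "Z3"), c("Z1", "Z2", "Z3"),
                            horizon = 0.02, n_boot = 0, compute_nri = FALSE)
  sub <- cc[cc$z2_observed == 1, ]
  set.seed(45)
  ref <- full_discrimination(sub, c("Z1", "Z3"), c("Z1", "Z2", "Z3"),
                             horizon = 0.02, n_boot = 0, compute_nri = FALSE)
  expect_equal(r$c1$estimate, ref$c1$estimate)
  expect_equal(r$idi$estimate, ref$idi$estimate)
})
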