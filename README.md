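# ccmi — multiple imputation for case-cohort survival data

`ccmi` analyses **case-cohort** studies: two-phase designs in which an
expensive covariate (the *phase-2* variable, e.g. a biomarker assayed from
stored blood) is measured only for the subjects who develop the event of
interest (the cases) and for a randomly drawn — here, stratified —
**subcohort**, while inexpensive *phase-1* covariates are observed for the
whole cohort.  The missingness this design creates is *missing at random by
design*: the probability that the phase-2 value is observed depends only on
case status and the stratification variables.

The package provides two estimation routes and the machinery to compare
them:

* **Multiple imputation (MI).**  A linear (or multinomial) imputation model
  for the phase-2 variable is fitted on the completely observed subjects —
  always including the case indicator and the stratum indicators — and `M`
  completed cohorts are drawn *properly*: the residual variance is drawn
  from its scaled inverse-chi-square distribution, the coefficients from
  their normal distribution given that draw, and each missing value from
  the resulting predictive distribution.  Per-imputation estimates
  `θ̂_m` with variances `V̂(θ̂_m)` are pooled by **Rubin's rules**:

  ```
  θ̂_MI = (1/M) Σ θ̂_m
  V̂(θ̂_MI) = W + (1 + 1/M) B,   W = (1/M) Σ V̂(θ̂_m),
                                 B = (1/(M-1)) Σ (θ̂_m − θ̂_MI)²
  ```

  with the fraction of missing information `(1+1/M)B / V̂(θ̂_MI)` and
  Rubin's small-sample degrees of freedom for Wald tests.

* **Borgan II weighted Cox estimator.**  The classical comparator: a
  weighted partial likelihood over the completely observed subjects with
  weight 1 for cases and, for subcohort non-cases of stratum *s*, the
  stratum-specific inverse sampling fraction (cohort non-cases in *s* /
  sampled non-cases in *s*), with a robust (dfbeta sandwich) variance.

On top of the hazard-ratio machinery, `ccmi` estimates **predictive
ability** — the quantities that motivate measuring the biomarker at all:

* **Harrell's C** with the usable-pair rule (two uncensored subjects, or an
  uncensored subject paired with one censored at or after the former's
  event), `C = π_c / (π_c + π_d)`;
* **Δ = C₂ − C₁**, the gain in C from adding the phase-2 variable to the
  phase-1 model, with a subject-bootstrap estimate of its
  within-imputation variance (no analytic form exists);
* **NRI** (net reclassification improvement, needs a-priori risk
  categories) and **IDI** (integrated discrimination improvement, the
  difference in discrimination slopes), computed from predicted event
  probabilities `1 − S(τ | covariates)` at a fixed horizon.

All of these are computed per imputed cohort and pooled with the same
Rubin machinery (`mi_discrimination()`), or computed naively on the
case-cohort subsample (`naive_discrimination()`) to document the bias the
naive approach incurs: the naive C shrinks as the subcohort shrinks, while
the MI estimate does not.

A simulator (`scenario_config()`, `simulate_cohort()`,
`draw_case_cohort()`) generates cohorts with exponential survival
`λ = exp(β₁Z₁ + β₂Z₂ + β₃Z₃)`, uniform censoring on `(0, τ)`, a noisy
surrogate of the phase-2 variable, and 3×3 tertile strata; a Monte-Carlo
harness (`run_estimation_study()`, `run_discrimination_study()`) replicates
whole experiments and emits bias / efficiency / power tables.

## Worked example

```r
library(ccmi)

cfg <- scenario_config(N = 10000, seed = 1)    # all betas log(2), tau 0.025
cohort <- simulate_cohort(cfg)
cc <- draw_case_cohort(cohort, 1000)           # stratified subcohort of 1000

fit_borgan(cc, c("Z1", "Z2", "Z3"))
#> Proportional-hazards fit (weighted partial likelihood), 1305 subjects, 336 events
#>      coef exp(coef)     se robust_se
#> Z1 0.4016    1.4943 0.1137    0.1536
#> Z2 0.7589    2.1360 0.0585    0.0774
#> Z3 0.7242    2.0631 0.0572    0.0840
#> loglik = -2728.763 (null -2927.166), converged: TRUE

spec <- imputation_spec()                       # Z2 ~ case indicator + strata
impfit <- fit_imputation_model(cc, spec)
fits <- lapply(draw_imputations(cc, impfit, M = 5), fit_cox,
               covariates = c("Z1", "Z2", "Z3"))
pool_rubin(lapply(fits, coef), lapply(fits, vcov))
#> Rubin-pooled estimate over M = 5 imputations
#>    estimate     se    fmi         df
#> Z1   0.6066 0.1144 0.0123 26644.0577
#> Z2   0.7314 0.0796 0.4957    16.2788
#> Z3   0.6751 0.0602 0.1404   202.9327
```

All true log hazard ratios are `log 2 = 0.693`.  In this single sample the
weighted estimate of the `Z1` effect happens to fall low (0.40, though its
robust 95% CI covers the truth), while the MI estimate (0.61) sits closer
and has a markedly smaller standard error (0.114 vs 0.154) — the phase-1
efficiency gain MI is used for.  The fraction of missing information is
substantial only for the partially observed `Z2`.

```r
set.seed(2)
mi_discrimination(cc, spec, covs1 = c("Z1", "Z3"),
                  covs2 = c("Z1", "Z2", "Z3"), horizon = cfg$tau, M = 5)
#> Predictive ability (mi, M = 5)
#>   C1      0.7190  (SE 0.0152, p = 0)
#>   C2      0.7833  (SE 0.0131, p = 3.79e-191)
#>   DELTA   0.0643  (SE 0.0117, p = 1.03e-07)
#>   NRI     0.2280  (SE 0.0281, p = 6.42e-15)
#>   IDI     0.0576  (SE 0.0101, p = 5.78e-05)
```

Adding the phase-2 variable raises the pooled Harrell C from 0.719 to
0.783 (Δ ≈ 0.064 with bootstrap-within-imputation SE 0.012, rejected at
the 5% level), with concordant NRI and IDI gains.

## Command line

```sh
Rscript -e 'ccmi::cc_cli()' simulate --config cfg.json --out cohort.csv
Rscript -e 'ccmi::cc_cli()' sample --in cohort.csv --size 1000 --seed 2 --out cc.csv
Rscript -e 'ccmi::cc_cli()' fit --in cc.csv --method mi --M 5 --seed 3 --out fit.json
Rscript -e 'ccmi::cc_cli()' study-discrimination --config cfg.json --reps 100 --out results/
```

(An equivalent launcher script is installed under `exec/ccmi`.)

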