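Package: ccmi
Title: Multiple Imputation and Weighted Estimation for Case-Cohort
    Survival Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of case-cohort survival data where an expensive
    phase-2 covariate is measured only on the cases and a stratified
    random subcohort.  Provides proper multiple imputation of the
    phase-2 covariate with Rubin's rules for pooling hazard ratios, a
    Borgan II stratified inverse-probability-weighted Cox estimator as
    comparator, and predictive-ability measures (Harrell's concordance
    index with the usable-pair rule, the difference in C between nested
    models with bootstrap-within-imputation variance, net
    reclassification improvement and integrated discrimination
    improvement).  Includes a cohort simulator and a Monte-Carlo study
    harness for bias, efficiency and power experiments, plus a small
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
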