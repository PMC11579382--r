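Package: trajgwas
Title: Nonlinear Growth Trajectory Modelling and GWAS of Derived Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A framework for genome-wide association studies of traits that
    change nonlinearly with age, illustrated with childhood body mass index.
    Cleans longitudinal height and weight records with a transparent
    implausible-value flag taxonomy, fits sex-stratified spline linear mixed
    models with optional continuous AR(1) within-subject correlation, selects
    and refines a preferred model over a candidate grid, derives per-child
    trajectory phenotypes (adiposity peak and rebound, window slopes and
    areas under the log-BMI curve) from the fixed coefficients and best
    linear unbiased predictors, and runs per-cohort additive-dosage GWAS
    followed by inverse-variance fixed-effects meta-analysis with
    heterogeneity statistics. A synthetic-cohort generator with known ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    nlme,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
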