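Package: tractplast
Title: Multivariate Along-Tract Analysis of White-Matter Plasticity from
    Quantitative MRI Tract Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting behaviorally relevant white-matter
    microstructural plasticity from along-tract multi-contrast quantitative
    MRI profiles. Implements segment-wise repeated-measures ASCA (per-metric
    linear mixed models whose fixed time-effect matrices are decomposed by
    PCA) with cluster-bootstrap BCa confidence intervals, calibrated
    aggregate g-ratio mapping from magnetization transfer and NODDI volume
    fractions, Olkin-Pratt fixed-effect pooling of interval rank
    correlations, a Monte Carlo familywise-error null for correlated
    significance criteria, and a network-level stage combining PCA
    factorability diagnostics, robust MM regression and leave-one-out
    cross-validation. A synthetic-cohort generator reproduces the
    longitudinal structure the analysis assumes so every stage is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
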