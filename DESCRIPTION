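Package: dvmsq
Title: Scoring, Caseness Classification, and Psychometrics for the
    Duke-Vanderbilt Misophonia Screening Questionnaire
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the Duke-Vanderbilt Misophonia Screening
    Questionnaire (DVMSQ), a brief self-report screen for misophonia. Implements
    total/subscale scoring and the criterion-based diagnostic algorithm
    (clinical, subclinical, none), the bifactor graded response measurement
    model with published general-population and autistic-sample parameter sets,
    simulation of synthetic respondents with screening zero-inflation and
    planted differential item functioning (DIF), maximum marginal likelihood
    calibration by an EM algorithm with bifactor dimension reduction, local fit
    diagnostics (residual correlations, SRMR, Q3 with parametric-bootstrap
    cutoffs), iterative Wald-test DIF/DTF analysis with Meade effect sizes, and
    the validity statistics used in instrument evaluation (polyserial and
    polychoric correlations, coefficient alpha, bifactor reliability indices,
    dependent-correlation confidence intervals, Cohen's d and odds ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    mvtnorm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
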