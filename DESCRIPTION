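Package: lifespiro
Title: Life-Course Lung Function Trajectories from Accelerated Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to derive life-course trajectories of spirometric lung
    function (FEV1, FVC, FEV1/FVC) from pooled longitudinal cohorts with an
    accelerated design. Provides a seeded synthetic-cohort generator with
    known piecewise-linear ground truth, harmonisation of visit-level risk
    factors (asthma, smoking, obesity) into life-course categories,
    height-and-study standardisation of lung function within age strata,
    cross-classified linear mixed models with natural-cubic-spline age
    effects and BIC elbow knot selection, year-by-year trajectory
    prediction, a Bayesian piecewise-linear changepoint decomposition that
    reports breakpoints, segment slopes, plateaus and peak age, and
    covariate-balancing propensity weights for loss to follow-up.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    splines,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
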