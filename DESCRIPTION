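Package: hba1ctraj
Title: Latent Class HbA1c Trajectory Modelling and Heart Failure Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting latent classes of longitudinal HbA1c
    trajectories measured from the time of type 2 diabetes diagnosis and for
    quantifying their association with first hospitalization for heart
    failure. Provides a synthetic registry generator emulating a hospital
    diabetes registry, cohort construction with diagnosis-date imputation and
    eligibility filtering, a latent class growth analysis (finite mixture of
    fixed-effect growth curves) engine fitted by multi-start EM with
    BIC/entropy/APPA model selection, from-scratch survival estimators
    (Kaplan-Meier, log-rank, Cox proportional hazards with Efron ties,
    Harrell's concordance), and pipeline drivers for baseline-shift and
    seed-sensitivity analyses and split-sample predictive validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
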