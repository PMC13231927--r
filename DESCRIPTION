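Package: pedvanc
Title: Pediatric Vancomycin Population Pharmacokinetics, Simulation and
    Precision Dosing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-compartment population pharmacokinetic model of intravenous
    vancomycin in children (3 months to 18 years) with allometric size
    scaling, sigmoidal postmenstrual-age maturation and an age-standardized
    serum creatinine effect on clearance. Provides closed-form
    concentration and AUC computation for arbitrary infusion regimens,
    virtual-cohort generation, Monte Carlo probability-of-target-attainment
    (AUC/MIC) simulation and dose-escalation optimization, empirical-Bayes
    (MAP) individual estimation for model-informed precision dosing, a
    scaled-down FOCE-I population estimator with nonparametric bootstrap,
    and model diagnostics (CWRES, goodness-of-fit tables,
    prediction-corrected visual predictive checks).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
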