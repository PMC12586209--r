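Package: femfall
Title: DXA-Based Femoral Strength, Soft-Tissue Thickness and Hip Fracture
    Risk Stratification in Synthetic Multi-Ethnic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying hip-fracture risk biomarkers in older adults:
    a calibrated synthetic-cohort generator (per sex and ethnicity marginal
    means, age trends and cross-correlations), parametric proximal-femur
    density phantoms with areal-BMD projection, a bone density to Young's
    modulus material-mapping chain with partial-volume correction, a
    tetrahedral finite-element solver for sideways-fall femoral strength,
    sex- and ethnicity-specific standing trochanteric soft tissue thickness
    prediction, cohort statistics (pooled means, one-way ANOVA, age-adjusted
    ANCOVA means, LOWESS age trajectories with bootstrap bands), and
    threshold-based cross-classification of fracture risk by T-score,
    FRAX hip-fracture probability and femoral strength.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
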