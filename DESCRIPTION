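Package: oscarpanel
Title: Serum Biomarker Quartile Patterns and Clinical Outcomes in COPD
Version: 0.1.0
Authors@R: person("OSCAR", "Maintainers", email = "maintainers@oscarpanel.org",
    role = c("aut", "cre"))
Description: Tools for relating serum biomarker panels to clinically important
    outcomes in chronic obstructive pulmonary disease (COPD). Implements
    quartile extreme-group stratification, classification of upper-versus-lower
    quartile outcome differences against minimal clinically important
    differences (MCID) with statistical fallback tests, the color-coded OSCAR
    (ObServed Clinical Association Results) heatmap, Spearman association
    matrices, GOLD-stage trend tests, and concordance statistics for three-year
    mortality. Ships a Gaussian-copula synthetic cohort generator calibrated to
    published GOLD-stage-stratified marginals and a published biomarker rank
    correlation matrix, so the full pipeline runs and is testable without
    patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
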