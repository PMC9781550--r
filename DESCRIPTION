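Package: pgxdose
Title: Pharmacogenetic Dose Adjustment via Bayesian Shrinkage of Activity-Score Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates quantitative dose adjustments for pharmacogenetic
    metabolizer phenotypes from published pharmacokinetic study data.
    Sampling points (one reported percent dose adjustment per study,
    substance and CYP2C19 phenotype group) are modelled with a
    sample-size-weighted two-component variance, phenotype activity
    scores are estimated from a phenotype-factor model with study-design
    pooling confounders, and per-substance activity-score slopes are
    fitted under four prior regimes: fixed effects, a Gaussian random
    effect, the horseshoe, and the regularized horseshoe. Includes a
    synthetic sampling-point generator with ground truth for recovery
    and calibration studies, a weighted-means baseline, study-property
    screening, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
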