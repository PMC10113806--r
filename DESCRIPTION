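Package: quadconf
Title: Unequal-Variance Signal Detection and Quadratic Confidence Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for multi-task perceptual confidence
    studies in which two-choice evidence distributions may have unequal
    variances (detection-like tasks). Provides an unequal-variance signal
    detection core (log-likelihood ratios, rating simulation, type-1 zROC
    slopes, response-conditional type-2 ROC areas), a synthetic-data generator
    (dynamic grating-in-noise stimuli, calibrated multi-task sessions, ROI
    time series with linear and quadratic confidence modulations, multivoxel
    condition patterns), confidence GLM design matrices (quadratic-confidence
    and categorical forms with a bias-controlled two-step polynomial fit),
    representational similarity analysis with theory-specified dissimilarity
    matrices, cross-run empirical RDMs, noise ceilings and an 18 sub-RDM
    regression, plus group-level statistics including JZS Bayes factors.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    digest,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
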