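Package: cardiopop
Title: Populations of Electro-Mechanical Human Ventricular Cardiomyocyte Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generation, calibration and stress-testing of populations of
    electro-mechanical human ventricular cardiomyocyte models. Provides a paced
    ordinary-differential-equation cell simulator with eleven scalable ionic and
    calcium-handling parameters and a contractile block with mechano-calcium
    feedback; extraction of action potential, calcium-transient and force
    biomarkers; detection of excitation and contraction abnormalities;
    history-matching calibration with Gaussian-process emulators and an
    implausibility (NROY) filter; staged mechanical re-calibration under varied
    preload and afterload; pore-block drug testing with abnormality-event
    counting; and population-level statistics (parameter summaries, Pearson
    correlations, Wasserstein distances, logistic accept/reject classifiers,
    odds ratios and uniparametric sensitivity analysis).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    pROC,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
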