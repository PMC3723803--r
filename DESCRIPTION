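Package: aoabreak
Title: Piecewise Regression and Correct Inference for Age-of-Acquisition
    Effects on Ultimate Attainment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing the 'flattened slope' prediction of the
    critical period hypothesis in second language acquisition. Fits joined
    piecewise (breakpoint) linear regressions of grammaticality-judgement
    scores on age of onset of acquisition, locates the optimal breakpoint by
    deviance minimisation over a grid, and compares nested models by
    one-tailed F-tests, AIC and BIC. Includes the inferential tools whose
    misuse the piecewise approach replaces: Fisher r-to-z comparison of
    independent correlations, partial correlations from zero-order
    correlations, significance tests for correlation coefficients, and exact
    noncentral-t power analysis for two-sample designs with unequal group
    sizes. Robustness checks (Huber M-estimation, generalised least squares
    with variance increasing linearly in age, outlier-excluded refits), a
    synthetic-data generator for the canonical critical-period mean shapes,
    and an end-to-end reanalysis pipeline with a command-line interface are
    provided.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
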