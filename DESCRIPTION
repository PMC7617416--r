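Package: disparityprf
Title: Population Receptive Field Analysis of Binocular Disparity Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating one-dimensional Gaussian disparity tuning
    curves (population receptive fields) from BOLD time series, and for
    relating the resulting tuning widths to psychophysical stereoacuity.
    Includes generation of log-scaled, zero-sum disparity stimulus
    sequences; a two-stage (exhaustive grid search plus nonlinear
    refinement) tuning-curve fitter with hemodynamic response function
    convolution; population-level analyses of tuning width versus preferred
    disparity using AICc model comparison; a simulated two-stage
    stereoacuity procedure (transformed up-down staircase followed by dual
    QUEST adaptive estimation with a Weibull observer); disparity
    resolution-limit computation and Spearman brain-behavior correlation;
    and a synthetic-data generator with known ground truth for end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
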