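Package: fertresp
Title: Non-Structural and Quadratic Fertilizer Response Models for Yield Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits two unary fertilizer dose-response models to small field-trial
    tables of application rate versus mean grain yield: the non-structural
    response model Y = A(s0+X)exp(-cX), estimated by separable (variable
    projection) nonlinear least squares, and the classical quadratic polynomial
    model Y = b0 + b1*X + b2*X^2, estimated by ordinary least squares. Provides
    marginal-yield (delta Y / delta X) analysis with linear and exponential
    marginal models, goodness-of-fit statistics, agronomic-maximum and
    economic-optimum rate recommendation (including the fixed-point iteration
    for the economic rate), typicality diagnostics for quadratic fits, batch
    model comparison with recommendation correlations, trial simulation and
    parameter-recovery experiments, and a command-line interface. Ships
    transcribed rice and winter-wheat N/P/K trials together with the published
    reference coefficient tables for those trials.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: graphics, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
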