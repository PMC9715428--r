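Package: cd34yield
Title: Predicting First-Day Apheresis CD34+ Yield from Circulating CD34+
    Counts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Models the relationship between the circulating CD34+ cell
    concentration measured immediately before the first apheresis session
    (PB-CD34+, 10^6 cells/L) and the CD34+ cell dose collected that day
    (AP-CD34+, 10^6 cells/kg) in stem-cell mobilization for autologous
    transplant.  Fits linear yield models by maximum likelihood under
    homogeneous, proportional, or combined (additive-plus-proportional)
    residual-error structures; selects the error structure and
    intercept-shift covariates by AIC; computes threshold-exceedance
    probabilities and inverts them in closed form for the minimal
    circulating count attaining a target collection probability; attaches
    case-resampling percentile-bootstrap confidence intervals; summarises
    calibration with exact binomial intervals; and generates synthetic
    pediatric mobilization cohorts for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
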