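Package: pelbayes
Title: Bayesian Cue Combination for Perceived Eye Level
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gaussian cue-combination modelling of perceived eye level (PEL):
    closed-form fusion of a body-referenced prior with pitched-line visual
    likelihoods, calibration of prior and likelihood variances from dark-trial
    settings and single-line regression slopes, the Matin-Li behavioural model
    as a comparison baseline, additive-versus-averaging regime analysis, a
    seeded synthetic Bayesian-observer simulator, prediction-error metrics, and
    CSV/CLI tooling for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
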