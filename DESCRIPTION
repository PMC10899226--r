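Package: audioprog
Title: Audiometric Progression Modelling for Hereditary Hearing Loss
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for cross-sectional audiometric progression analysis in
    hereditary sensorineural hearing loss. Reads tidy audiogram tables,
    computes binaural averages, pure-tone averages and frequency-band means,
    fits and compares threshold-versus-age regression models (power, linear,
    logarithmic, quadratic), inverts fitted curves to estimate onset age
    (25 dB crossing) and hearing progression time (25 to 60 dB), and compares
    annual threshold deterioration between mutation-domain groups with a
    seeded label-permutation test. Includes a synthetic cohort generator that
    emulates power-law audiogram progression so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
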