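Package: odorblend
Title: Binary Odor Mixture Interaction Modelling by Tangent-Intercept
    Partial Odor Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for modelling the odor interaction of binary odorant
    mixtures from gas-phase concentrations and odor detection thresholds.
    Computes odor activity values (OAV) and their natural logarithms, fits
    the linear odor-intensity response of individual odorants, normalizes
    binary-mixture samples to (mixing proportion, intensity per lnOAV unit)
    coordinates, fits the quadratic mixture curve with pointwise confidence
    bands, decomposes mixture odor intensity into per-component partial
    intensities by the tangent-intercept construction borrowed from partial
    molar volume analysis, and predicts the joint odor intensity of binary
    mixtures. Includes a synthetic sensory-panel simulator (half-step odor
    intensity referencing scale ratings with assessor noise) so that
    fitting, prediction and precision analyses can be exercised without a
    human panel, plus CSV/JSON readers and writers and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
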