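Package: fermwatch
Title: Fault Diagnosis for Batch Glutamate Fermentation via Additive
    Models and Residual-Bootstrap Prediction Bands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online fault diagnosis for batch fermentation processes with
    small sample sets. Fits a generalized additive model (penalized cubic
    regression splines, GCV smoothing selection) relating offline glutamate
    titre to online process parameters (fermentation time, dissolved oxygen,
    oxygen uptake rate, carbon dioxide evolution rate), quantifies the
    uncertainty of the model estimate with residual-bootstrap prediction
    bands, and flags fault intervals whenever the online-estimated
    production leaves the band. Includes a synthetic fermentation-batch
    generator with configurable fault injection (stirring-speed drop,
    nitrogen-source substitution) so the whole pipeline is testable without
    fermenter data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
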