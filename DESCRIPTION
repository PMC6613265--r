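Package: lumikin
Title: Kinetic Modelling and Rhythm Analysis of Luciferase Fusion Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative interpretation of bioluminescent
    protein-fusion reporters in plant circadian experiments. Simulates and
    fits a pair of periodically forced linear ordinary differential
    equations describing NanoLUC and firefly luciferase (FLUC) fusion
    signals, estimates first-order enzyme-stability decay rates with Q10
    temperature scaling and calibrator-age correction, builds log-log
    calibration curves from serial dilutions with linearity and
    matrix-inhibition diagnostics, and estimates period, phase and
    amplitude of luminescence traces by an FFT-seeded cosine least-squares
    fit. A synthetic plate-reader data generator (counting plus
    multiplicative noise) makes every stage testable without laboratory
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
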