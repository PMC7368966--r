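Package: nirwaveband
Title: Waveband Selection and Genetic Optimization for Near-Infrared
    Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative calibration of near-infrared (NIR) spectra against
    a reference analyte value, with a three-stage waveband optimization
    pipeline: an exhaustive grid-search moving-window scan that ranks
    contiguous wavebands by held-out validation error of a partial least
    squares (PLS) model, principal-component transformation of the selected
    wavebands into latent components, and a binary genetic algorithm that
    performs secondary variable selection over those components with a
    parametric scan of crossover and mutation rates. Includes standard
    normal variate (SNV) preprocessing, SPXY (joint x-y distance) sample
    set partitioning, NIPALS PLS1 regression, a synthetic NIR mixture
    spectrum simulator with known ground truth, and a command-line
    interface over the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
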