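Package: optoflow
Title: Quantitative Analysis of Optically Patterned Active Microtubule Fluids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-lapse fluorescence microscopy of
    light-controlled microtubule-kinesin active fluids. Provides particle
    image velocimetry (PIV) with subpixel peak refinement and normalized
    median outlier filtering, structure-tensor orientation fields and mean
    bend-angle traces, photoswitching kinetics fits (exponential activation,
    logistic deactivation), a bend-angle relaxation model combining motor
    unbinding and elastic recovery, accumulated-strain analysis with
    quiescent/sliding/buckling regime classification, and the
    confinement-dependent instability threshold model linking activation
    intensity to an effective activity parameter. A seeded synthetic-data
    generator renders advected filamentous textures, speed and angle traces,
    and threshold datasets so every stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
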