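Package: emgshift
Title: Simulation and Decoding of Surface EMG Under Arm-Position Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying the limb-position effect in myoelectric
    gesture decoding. Provides a protocol-faithful simulator of 16-channel
    surface electromyography recorded during grasp holds at nine forearm
    positions, readers and writers for the trial-indexed HDF5 session
    layout used by public arm-translation datasets, Butterworth/notch
    preprocessing with sliding-window Hudgins time-domain features, a
    regularised linear discriminant engine, within- and cross-position
    classification experiments, and a hierarchical multi-label classifier
    that routes grasp decoding through a position encoder, with strict and
    soft evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    rhdf5,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
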