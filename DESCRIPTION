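Package: fluortea
Title: Fluorescence-Spectral Screening of Tea Adulteration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Chemometric workflow for detecting adulteration of Tieguanyin
    oolong tea (and its degree) from 475-1000 nm fluorescence spectra.
    Provides row-wise spectral pretreatments (standard normal variate,
    multiplicative scatter correction, Savitzky-Golay smoothing), four
    PLS-based characteristic-wavelength selectors (successive projections
    algorithm, competitive adaptive reweighted sampling, random frog,
    uninformative variable elimination), polynomial-kernel support vector
    machine discriminant models for the 2-class (pure vs adulterated) and
    6-class (adulteration degree) tasks, confusion-matrix evaluation
    metrics, and a synthetic mixture-spectra generator that emulates the
    chlorophyll-like emission shape and measurement artefacts of the
    original study design, so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
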