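Package: aquaspec
Title: Uncertainty-Aware Optical Water-Quality Assessment and Algal Bloom Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for assessing surface-water quality from multi-modality
    optical spectra (UV/Vis transmission, fluorescence under 440 nm and
    590 nm excitation, scattered light under 850 nm excitation). Implements
    spectral preprocessing (blank handling, absorbance conversion,
    temperature normalization, zero-phase FIR smoothing, turbidity
    compensation), full-spectrum conformity features as coefficients of
    determination against Gaussian-sum reference spectra, GUM-style expanded
    measurement uncertainty, and a Bocklisch-type fuzzy pattern classifier
    whose membership fuzziness encodes the expanded uncertainty. Includes a
    seeded synthetic-data generator emulating the instrument so the whole
    chain is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
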