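Package: sfphase
Title: Spatial-Frequency Spectra of Cortical Phase Dynamics on Irregular Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the spatial-frequency spectrum of the phase of
    band-limited cortical field activity measured on sparse, irregular
    contact arrays embedded in a folded surface (stereotactic EEG style
    recordings). Phase is extracted with short two-cycle Morlet wavelets
    at log-spaced temporal frequencies, decomposed by complex singular
    value decomposition into spatial covariance patterns, and quantified
    by multi-scale finite differencing over approximately equilateral
    triangles of contacts with geodesic edge lengths. Includes
    standing-wave (DC) removal, surrogate-testing machinery (spherical
    phase-gradient injection, singular-weight reversal, sensor
    sparsification, average-reference loading), permutation statistics
    for log-log wavelength-power regressions, and a synthetic-data
    generator for meshes, depth-electrode arrays and wave recordings
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
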