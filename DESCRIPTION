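Package: flimphasor
Title: Fit-Free Phasor Analysis of Time-Domain FLIM Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Headless phasor analysis of time-domain fluorescence lifetime
    imaging microscopy (FLIM) data. Reads multi-page TIFF stacks of per-pixel
    photon-arrival histograms, transforms each pixel to phasor coordinates
    (g, s) at a harmonic of the laser repetition rate, calibrates against a
    reference standard of known single-exponential lifetime, and derives
    phase and modulation lifetime maps, distance-from-species and
    two-component fraction maps. Includes reversible median filtering and
    intensity/contrast thresholding, ROI statistics, phasor-plot and map
    rendering, batch processing, a command-line interface, and a synthetic
    decay generator with known ground truth so the whole pipeline can be
    validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tiff,
    jsonlite,
    yaml,
    optparse,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    withr,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
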