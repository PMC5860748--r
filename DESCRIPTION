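Package: bundlerheo
Title: Active Microrheology of Single Semiflexible Filament Bundles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Frequency-resolved bending stiffness of single semiflexible
    filament bundles (e.g., depletion-force bundled actin) from the spatial
    decay of an actively driven transverse oscillation.  Implements the
    overdamped driven-beam model at low Reynolds number, a finite-difference
    reference solver, a seeded synthetic fluorescence-microscopy renderer
    with ground truth, subpixel contour tracking, Fourier band-pass
    amplitude extraction, hydrodynamic-length fitting, and power-law regime
    classification distinguishing wormlike-chain from wormlike-bundle
    scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Matrix,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
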