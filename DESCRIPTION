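Package: sed3d
Title: Three-Dimensional Fibril Orientation Mapping from Scanning
    Electron Diffraction Tilt Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs per-pixel three-dimensional fibril axes from
    scanning electron diffraction (4D-STEM) data acquired at a few tilt
    angles about a single axis. Each diffraction pattern is reduced to a
    Bragg-peak azimuth at the cellulose (200) ring using 360 virtual
    detectors, scored by a Fourier quality ratio, aligned across tilts by
    projective registration, and back-rotated into a common zero-tilt
    frame; the fibril axis at each pixel is the direction best-orthogonal
    to all measured q-vectors, found by an iterative averaged-projections
    solver. Includes angle conventions and layer statistics for helical
    cell-wall textures (handedness classification, helix pitch), a
    synthetic phantom and diffraction forward model for validation,
    colour-wheel and cylinder-glyph visualisation, and an HDF5-based
    pipeline with a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    graphics,
    jsonlite,
    png,
    rhdf5,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
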