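Package: smartRotate
Title: Smart Rotation Planning for Multi-View Light-Sheet Microscopy
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies per-view information content in multi-view selective
    plane illumination microscopy (SPIM) with a block-wise DCT-II spectral
    entropy metric, registers per-view projections into a sample-fixed frame,
    builds angular sample-response profiles, fits a von Mises coverage model
    (amplitude = fluorophore content, concentration = optical accessibility)
    to each angular region, and selects the set of rotation angles that
    maximizes predicted sample coverage. Includes a synthetic multi-view SPIM
    simulator (embryo-like phantoms with angularly inhomogeneous fluorophore
    density, optical obstructions, Beer-Lambert attenuation, depth-dependent
    blur and Poisson-Gaussian noise) used to validate the workflow end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
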