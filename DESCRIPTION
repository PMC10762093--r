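Package: vesiclefusion
Title: Diffuse-Interface Minimal Energy Pathways for Lipid Vesicle Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phase-field (Ginzburg-Landau) model of fluid lipid vesicle
    mechanics that recovers the Canham-Helfrich elastic energy in the
    sharp-interface limit while remaining able to change membrane topology.
    Implements the bending and Gaussian-curvature functionals on an
    axisymmetric cell-centered spectral grid, a locally variable Gaussian
    modulus carried by an auxiliary phase field, augmented-Lagrangian
    constraints on area, volume and patch area, semi-implicit constrained
    gradient flow, and the zero-temperature string method for computing
    minimal energy pathways of vesicle fusion, including hemifusion
    intermediates and fusion energy barriers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
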