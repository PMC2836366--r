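Package: magnetocell
Title: Magnetically Induced Transmembrane Potentials in a Two-Shell Spherical Cell
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analytical quasi-static model of a spherical cell containing a
    concentric spherical organelle (e.g. a mitochondrion) exposed to a
    sinusoidal magnetic field. Solves the degree-1 spherical-harmonic Laplace
    boundary-value problem across five homogeneous dielectric regions with
    complex conductivities, yielding the complex transmembrane potentials on
    the cytoplasmic and organelle membranes. Provides frequency responses,
    membrane-removal ("shielding") comparisons, parameter-by-frequency sweeps,
    surface polarization maps, the low-frequency phase-transition radius of
    the organelle, an independent transfer-matrix verification route,
    boundary-residual diagnostics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    tools,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
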