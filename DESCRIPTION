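Package: eqnnp
Title: Equivariant Neural Network Potentials with Force-Field Long-Range Terms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid machine-learning/force-field interatomic potential for
    molecular simulation. A strictly local equivariant pair embedding with a
    smooth periodic-table positional encoding of chemical species feeds
    multi-output heads predicting local energies, antisymmetrized charge
    exchange and atom-in-molecule volume ratios. The head outputs
    parameterize physically motivated long-range terms: a charge-penetration
    damped Coulomb interaction (with Ewald summation under periodic boundary
    conditions) and Tkatchenko-Scheffler pairwise dispersion with
    environment-scaled C6 coefficients and van der Waals radii. The package
    includes a reverse-mode differentiation tape providing exact forces and
    force-matching gradients, a multi-stage training engine with a synthetic
    labeled-data generator, and a small molecular-dynamics engine (BAOAB
    Langevin NVT) with radial-distribution-function and dipole-spectrum
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
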