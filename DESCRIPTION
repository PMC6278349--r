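Package: hydrodecomp
Title: Hydration Free-Energy Decomposition and Modified Poisson-Boltzmann
    Models for Non-Polar Aromatic Hydrocarbons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for component-wise analysis of hydration free energies of
    rigid non-polar solutes. Implements the additive decomposition of the
    hydration free energy into reorganization, electrostatic, dispersion and
    cavitation terms with consistency checking of component tables;
    origin-constrained and ordinary least-squares fits for linear-response
    theory analysis of electrostatic and dispersion components; a
    Shrake-Rupley solvent-accessible surface-area engine with deterministic
    golden-spiral quadrature; surface-area-linear models of the
    non-electrostatic term, including a modified Poisson-Boltzmann style
    predictor with a rescaled linear-response coefficient and an
    intercept offset correction; Weeks-Chandler-Andersen splitting of
    Lennard-Jones potentials; mean-absolute and root-mean-square error
    scoring; and a seeded synthetic-data generator that emulates
    explicit-solvation component tables so that every pipeline stage is
    testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
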