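Package: hfecorr
Title: Element-Count and Partial Molar Volume Corrections for Hydration
    Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-hoc corrections for systematic errors in computed hydration
    free energies of small molecules. Implements the partial molar volume
    correction (PMVC), the element count correction (ECC), and their
    combination (PMVECC), fitted by ordinary least squares with leave-one-out
    cross-validation and bootstrap error analysis. Includes element counting
    from SDF, PDB, MOL2 and AMBER topology files, a two-state Bennett
    acceptance ratio free energy estimator, a rigid/flexible molecule
    classifier based on implicit-solvent energy traces, benchmark error
    statistics, and a synthetic-data generator with known ground truth for
    validating the fitting protocol.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
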