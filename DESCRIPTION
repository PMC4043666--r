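Package: qsrriso
Title: Recognition of Cis-Trans Isomers from Reversed-Phase Gradient
    Retention by QSRR Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for recognizing geometric (cis/trans) isomers of
    thiohydrazone benzenesulfonamides from reversed-phase liquid
    chromatography retention. Implements 3D-geometry-sensitive molecular
    descriptors (GETAWAY H and R autocorrelations, CATS2D
    pharmacophore-pair counts, 3D atom-pair distance sums), a
    linear-solvent-strength (LSS) gradient-elution model that extrapolates
    chromatographic lipophilicity (log kw) from two gradient runs and
    calibrates instrument dead and dwell times, forward stepwise multiple
    linear regression for quantitative structure-retention relationship
    (QSRR) model building, and accurate-mass shift annotation of
    hydroxylated and reductively debrominated metabolites. A synthetic-data
    generator produces torsion-flipped isomer pairs and retention tables
    with known ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    ChemmineR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
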