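Package: metris
Title: Rolling-Parameter Analysis for Mechanically Transduced Immunosorbent Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for mechanically transduced immunosorbent
    (METRIS) assays, in which protein-coated ferromagnetic beads ("rollers")
    are rotated on a protein-functionalized surface by an external magnetic
    field and the translational displacement per actuation reports on the
    effective friction, and hence the strength, of the protein-protein
    interaction. Provides a synthetic trajectory and image-stack generator
    with ground truth, a simple centroid tracker for sparse rollers,
    segmentation of trajectories into clockwise/counter-clockwise actuation
    windows, the dimensionless rolling parameter RP = dx / (pi D tau omega),
    an anchored log-log calibration of RP against dissociation constants with
    prediction intervals, extrapolation of dissociation constants from
    measured rolling parameters, scaling-factor correction against published
    affinities, free-energy differences (delta-delta-G) and fold changes, and
    two-sample comparison reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
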