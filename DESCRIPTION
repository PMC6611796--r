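Package: pktscreen
Title: Phagokinetic Track Screening and Cell Migration Phenotype Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification and statistical analysis of phagokinetic track
    (PKT) cell-migration screens. Cells migrating over a lawn of latex beads
    clear a track whose geometry reports migratory behaviour; the package
    segments and measures these tracks (net area, axial ratio, roughness and
    related morphometry), normalizes whole plates to mock-transfected
    controls with robust Z-scores, classifies knockdowns into migratory
    phenotype classes, calls and deconvolution-validates hits, analyzes
    single-cell trajectories from time-lapse movies via overlap tracking,
    and clusters single-cell morphology profiles. A seeded synthetic-data
    generator (persistent random walk motility, bead-lawn rendering, plate
    simulation) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
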