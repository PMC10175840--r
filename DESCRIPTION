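Package: nemoresponse
Title: CO2-Evoked Neural Activity and Locomotion Analysis for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for carbon dioxide-evoked responses in
    Caenorhabditis elegans across life stages: ratiometric (FRET) calcium
    trace quantification as percent dR/R0 with empirical-null classification
    of excitatory, inhibitory, and silent responses against air controls;
    centroid-trajectory locomotion analysis (instantaneous speed,
    forward/reverse/pause segmentation, stimulus-locked window metrics);
    chemotaxis-index summaries; a statistical comparison harness; and
    synthetic-data generators with known ground truth so every stage is
    testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
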