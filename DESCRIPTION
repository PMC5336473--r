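Package: pandensity
Title: Pan-Dataset Electron-Density Analysis for Crystallographic Fragment Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects partial-occupancy ligand-binding events in crystallographic
    fragment screens by contrasting each dataset's electron-density map against a
    statistical ground-state model built from many maps of the same crystal form.
    Provides CCP4/MRC map input/output on crystallographic voxel grids, Z-map
    outlier detection, background density correction (BDC) and event-map
    calculation, event-to-site clustering, ligand validation metrics (RSCC,
    RSZO/OCC, surroundings B-factor ratio), screen-level summaries, and a
    synthetic fragment-screen generator with ground-truth labels so the full
    pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
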