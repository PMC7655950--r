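Package: reefscape
Title: Object-Based Habitat Mapping and Current Statistics for Cold-Water Coral Reefs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising cold-water coral habitats from
    photogrammetry-derived rasters and near-bed current records. Provides a
    synthetic seabed scene and current-meter simulator with known ground
    truth, Horn slope/aspect derivation from digital elevation models,
    object-based image analysis (multiresolution region-merging segmentation,
    nearest-neighbour facies classification, confusion-matrix accuracy
    assessment), quality control and summary statistics for acoustic Doppler
    current profiler (ADCP) series (despiking, lander-topple detection, rose
    tables, threshold exceedance), and integration statistics joining the
    spatial and temporal products: facies proportions, live-coral aspect by
    circular mean, the coral-facing mean current speed, feeding-window time
    fractions and cross-site rank trends.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
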