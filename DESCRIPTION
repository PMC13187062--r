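Package: osteohist
Title: Histomorphometric Taxon Identification of Burned Bone Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-destructive taxonomic assessment of small burned (calcined)
    bone fragments from cortical-bone histomorphometry. Measures osteon
    (On.Ar) and Haversian-canal (H.Ar) cross-sectional areas from traced
    contours on calibrated micro-CT slice images, propagates burning-shrinkage
    uncertainty as interval bounds (no shrinkage at 500-600 degrees C, areas
    divided by 0.75 at ~700 degrees C), and compares fragments against a
    packaged mammalian reference database by bivariate range-rectangle overlap
    and pairwise Games-Howell tests computed from summary statistics.
    Includes synthetic generators for per-osteon area populations and
    annular-osteon slice images with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
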