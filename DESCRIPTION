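Package: mccquant
Title: Quantification of Plasma-Membrane Microdomain Patches and Yeast
    Sphingolipidomics Tables
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-cell quantification of punctate plasma-membrane
    microdomains (MCC/eisosomes) in equatorial fluorescence cross-sections
    of yeast cells: ellipse fitting of segmentation masks, membrane/interior
    intensity partitioning, circular membrane intensity profiles with peak
    (patch) detection and prominence, two-channel registration and Pearson
    colocalization, time-lapse patch-density decay with half-decay
    estimation, and dye-uptake ratios.  Includes post-processing of
    sphingolipid amount tables (inorganic-phosphate normalization, class
    pooling, log2 fold changes, PCA with per-lipid contributions,
    protein-lipid correlation), hierarchical replicate aggregation with the
    associated significance tests, and a ground-truthed synthetic-data
    generator for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
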