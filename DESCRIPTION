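Package: polarTrack
Title: Quantifying Polar Siderophore Accumulation in Bacterial Microcolonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell image analysis of polar accumulation of periplasmic
    fluorophores (such as the siderophore pyoverdin) in time-lapse microscopy
    of growing bacterial microcolonies. Provides an agent-based synthetic
    time-lapse generator with full ground truth, cell segmentation and
    geometry measurement, long-axis fluorescence profiles, a pole/center
    intensity-ratio statistic with a polarized/homogeneous classifier,
    lineage tracking with generation and pole-identity assignment, and
    growth-resumption kinetics (lag and depolarization times).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, Microscopy, SingleCell, Software
RoxygenNote: 7.3.3
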