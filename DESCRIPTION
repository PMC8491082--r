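Package: canopy3d
Title: Field-Scale LiDAR Canopy Phenotyping from 3D Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting per-plot canopy traits from field-scale
    LiDAR point clouds of cereal trials. Implements statistical outlier
    removal, ground classification and terrain flattening, TIN-based
    canopy height model (CHM) rasterization, automated plot segmentation
    via directional edge detection and Hough line fitting, plot-level
    trait analysis (top-decile height, canopy coverage, alpha-shape 3D
    surface area, voxel occupancy indices), a spectral canopy structural
    index derived from the 2D discrete Fourier transform of plot CHMs,
    nitrogen-response classification, and a weighted trait-ranking
    performance matrix. Includes a synthetic-field generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
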