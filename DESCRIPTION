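Package: cecseg
Title: Automated Corneal Endothelial Cell Segmentation and Density Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automated analysis of corneal endothelial specular
    microscopy images. Provides a centroid-supervised training pipeline for a
    small two-class U-Net border segmenter (label synthesis by
    marker-constrained watershed, 78x78 patch tiling with mirror
    augmentation), morphological post-processing with ungradable-image
    detection, a classical marker-driven watershed baseline (alternating
    sequential filter, h-dome, regional maxima), Voronoi-tessellation cell
    density estimation, centroid-tolerance benchmarking metrics, and a
    synthetic endothelial-mosaic generator with exact ground truth so the
    entire pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
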