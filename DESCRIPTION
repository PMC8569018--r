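Package: embryomorph
Title: Quantitative Whole-Embryo Phenotyping from Optical Projection Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantitative 3D phenotyping of whole
    zebrafish embryos imaged by optical projection tomography (OPT).
    Provides rotation-axis correction and filtered back-projection
    reconstruction of sinogram stacks, a two-scale normalized
    difference-of-Gaussians segmentation of embryo bodies, skeleton- and
    hull-based 3D morphometry producing a 26-descriptor feature vector per
    embryo, a PCA morphospace with severity clustering
    (hierarchical/k-means/k-medoids), and quantitation of signaling
    gradients from confocal stacks (nuclear segmentation, margin-distance
    intensity profiles with lowess fits, and signal-domain size ratios).
    A built-in phantom generator produces ground-truth embryo cohorts,
    forward-projected sinograms and synthetic nuclear gradient stacks so
    the whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    tiff,
    cluster,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    e1071,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
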