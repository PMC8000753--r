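Package: scaffembed
Title: Micro-CT Densitometry and Finite-Element Validation of Spiked-Scaffold
    Embedding in Trabecular Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for validating a linear finite-element model of a
    multi-spiked connecting scaffold press-fit into periarticular trabecular
    bone. Provides a parametric generator of the concentric-ring spike layout,
    synthetic micro-CT trabecular volumes and replicate embedding force-distance
    curves, the segmentation and densitometry chain (porosity extraction,
    single-voxel noise removal, pore classification, marrow fraction, mixture-
    rule bone density and the density-cubed longitudinal modulus), three-region
    force-curve analysis with region-II regression, a transversely isotropic
    hexahedral finite-element solver with Huber-von Mises-Hencky stress mapping
    and a densified-bone insert modification, and fraction-of-variance-
    unexplained (FVU) agreement testing between simulated and empirical
    embedding curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
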