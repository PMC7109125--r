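Package: canalseg
Title: Mandibular Canal Segmentation Toolkit for CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for segmenting the mandibular (inferior
    alveolar nerve) canal in cone-beam CT volumes: NIfTI and DICOM-series
    volume input, automatic mandible region-of-interest extraction by
    multi-level Otsu thresholding and 3D morphology, densification of sparse
    clinician canal tracings by cubic interpolation, compact 2D/3D
    encoder-decoder segmentation networks (SegNet and U-Net variants) with
    median-frequency class balancing and weighted cross-entropy, segmentation
    metrics in both the printed and the community-standard formulation, and a
    seeded synthetic CBCT phantom generator with analytic ground truth for
    testing every stage without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
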