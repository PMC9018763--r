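Package: dentseg
Title: Tooth Instance and Alveolar Bone Segmentation from CBCT-Like Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a two-branch system
    for segmenting individual teeth (with FDI numbering) and alveolar bones from
    3D cone-beam CT volumes. The tooth branch is hierarchical and
    morphology-guided: region-of-interest localization, per-voxel offset fields
    voting for tooth centroids and skeletons, density-peaks clustering into
    instances, and multi-task single-tooth segmentation with boundary and
    root-apex supervision plus FDI classification. The bone branch enhances
    boundaries with a 3D Haar detail filter and performs cascaded three-class
    segmentation (background, midface, mandible). Includes a seedable synthetic
    dental-phantom generator with full ground truth (instances, centroids,
    skeletons, boundaries, apices, bone classes, and missing-tooth,
    misalignment and metal-artifact abnormalities), a lightweight volumetric
    encoder-decoder network engine with training and early stopping, surface
    distance and overlap metrics, and tooth volume/intensity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
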