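Package: chopct
Title: Segmentation and Morphometry of the Embryonic Hindbrain Choroid Plexus in Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automated 3D segmentation of the embryonic hindbrain choroid
    plexus (HbChP) from contrast-enhanced micro-CT image stacks, and an
    automated morphometric criterion panel computed from the resulting binary
    masks: voxel-count volume, Crofton surface area, principal-axis outgrowth
    angle, ventricle proportion, rostrocaudal and lateral extent measures, and
    landmark-based Generalized Procrustes shape analysis. Includes a synthetic
    embryo-head phantom generator with ground-truth masks so the full pipeline
    can be exercised and validated offline, plus readers and writers for
    per-slice TIFF stacks, Slicer fiducial landmark files, binary STL surface
    meshes and CSV morphometry reports.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
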