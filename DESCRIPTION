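Package: cytoarch
Title: Staining-Free Brain Cytoarchitecture Quantification from Serial Section Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies mouse-brain cytoarchitecture from serial coronal
    section images in which cell nuclei appear as dark, round objects on a
    brighter autofluorescent background (as in serial two-photon tomography).
    Section images are tiled, nucleus-like objects are detected and stitched
    into per-section masks, detections are assigned to atlas regions and
    hemispheres, and per-region 3D cell density, volume, and count are
    estimated with an optical-slab model. Includes robust (MAD-based) quality
    control of brains and regions, batch correction of volumes, and
    population statistics: laterality screens, sex and strain dimorphism
    screens with Benjamini-Hochberg FDR control, linear-SVM sex prediction
    with feature ranking, and volume-density correlation structure. A
    phantom-brain generator with full ground truth supports validation of
    every stage at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
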