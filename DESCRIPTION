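Package: cribra3d
Title: 3D Reconstruction and Architecture Classification of Cribriform DCIS from Serial Histology Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated pipeline for reconstructing the three-dimensional
    luminal architecture of cribriform ductal carcinoma in situ (DCIS) from
    stacks of H&E-stained serial section images. Sections are rigidly registered
    by normalized cross-correlation template matching, ducts and intraductal
    microlumina (cribra) are segmented with a custom hue transform, Otsu
    thresholding and mathematical morphology, and the binary cribra masks are
    stacked into an isotropic voxel volume whose connected luminal components
    are classified as bubble-like, tube-like or unclear from their section-height
    extent. A synthetic H&E phantom generator with full ground truth (masks,
    rigid perturbations, architecture label) makes every stage testable in the
    absence of deposited tissue images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
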