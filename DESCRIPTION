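Package: octavasc
Title: Semi-Manual Vessel Density Analysis of OCTA En-Face Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the retinal superficial vascular plexus on
    en-face optical coherence tomography angiography (OCTA) images. Implements
    two semi-manual post-processing pipelines -- Mexican-hat (Laplacian of
    Gaussian) ridge binarization with manual foveal avascular zone removal, and
    Shanbhag information-measure histogram thresholding -- followed by
    morphological skeletonization. Computes Vessel Density, Skeleton Density
    and Vessel Diameter Index in the nine ETDRS macular sectors, image-quality
    metrics (noise reduction, vascular fragmentation, grid- and FAZ-placement
    repeatability errors) and Bland-Altman method-agreement statistics.
    Includes a seeded generator of fovea-centered vascular phantoms with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
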