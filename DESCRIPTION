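Package: polarflow
Title: Flow-Driven Endothelial Polarity and Vessel Regression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of endothelial cell polarity and vessel
    regression in planar vascular networks such as the postnatal mouse retina.
    Provides a synthetic retinal-plexus generator with known ground truth,
    centerline extraction with radius estimation from segmented lumen masks,
    a one-dimensional Poiseuille network flow solver with wall shear stress,
    nucleus-to-Golgi axial polarity statistics relative to local flow
    direction, radial density and shear profiling, and detection and staging
    of vessel regression profiles with apoptosis colocalization.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
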