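Package: nanometrics
Title: Quantitative Nanoscale Imaging Analysis of the Muscle Cell Cytoskeleton
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative nanoscale imaging of
    differentiating muscle cells. Measures cortical actin bundle widths
    (FWHM) from dSTORM single-molecule localization tables with
    localization-precision deconvolution, performs blind image-correlation
    drift correction, skeletonizes rendered superresolution images and
    quantifies actin-network branch morphometry, fits Young's moduli from
    AFM force-indentation curves with the Hertz contact model, and computes
    myotube differentiation and fusion indices from labeled segmentation
    masks. Includes seeded synthetic-scene generators with recorded ground
    truth so every analysis stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
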