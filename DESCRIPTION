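Package: icmap
Title: Quantitative Mapping of Intracytoplasmic Membrane Localization from
    Bacteriochlorophyll Autofluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell image analysis of bacteriochlorophyll (BChl)
    autofluorescence in purple nonsulfur bacteria. Provides a synthetic
    multi-channel micrograph generator with full ground truth, calibrated
    TIFF input/output with landmark-based inter-channel registration,
    phase-contrast cell segmentation with automated splitting of touching
    cells, medial-axis intensity profiling, detection and quantification of
    intracytoplasmic membrane (ICM) foci, adhesin-based cell pole
    orientation, population-level statistics (demographs, centroid maps,
    focus spacing regression, pole-distance conservation, localization
    pattern classification), and Fitch parsimony reconstruction of
    ICM traits on a species tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    ape,
    jsonlite,
    withr,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
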