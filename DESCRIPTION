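Package: hsiscore
Title: Quantification of Immunohistochemical Staining from Hyperspectral
    Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying chromogenic immunohistochemical
    staining (DAB with hematoxylin counterstain) from visible/near-infrared
    hyperspectral microscopy cubes. Provides reflectance calibration against
    dark and white reference frames, ENVI and multi-page TIFF cube I/O,
    principal-component false-colour visualisation and segmentation,
    correlation-function pixel classification against reference spectra,
    cell delineation with optical-density intensity binning, and per-core
    H-score and Allred scoring. Includes a Beer-Lambert synthetic-tissue
    generator with full ground truth for validation, and the agreement
    statistics used to compare scoring methods (Cohen's kappa with
    Landis-Koch interpretation, Spearman rank correlation, exact Wilcoxon
    signed-rank, Shapiro-Wilk).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
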