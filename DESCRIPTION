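Package: deband
Title: Removal of Vertical Band Defects from Digital Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and removes vertical band artifacts caused by detector
    malfunction in digital mammograms. Provides breast-contour and defect-core
    detection, per-column baseline flattening of the intensity ramp flanking
    the defect, contrast equalization of the degraded side with an adaptively
    chosen CLAHE clip limit, and restoration of the destroyed band by fusing
    per-row polynomial interpolation with diffusion inpainting through a
    binarized streak mask. Includes a seeded synthetic phantom generator,
    full-reference image quality metrics (SSIM, GMSD), a cut-strip restoration
    benchmark, first-order radiomics descriptors, and ANOVA/Tukey HSD
    feature-drift statistics for validating that restoration does not distort
    quantitative image features.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Matrix,
    png,
    tiff,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
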