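Package: tmeQIA
Title: Quantitative Immunohistochemistry Image Analysis and Tumor
    Microenvironment Typing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative image analysis of chromogenic PD-L1 and CD8
    immunohistochemistry: H-DAB color deconvolution in optical-density
    space, hematoxylin-based nuclei segmentation, per-cell bivariate
    (area, DAB intensity) gating, and the positive-cell ratio. Cohort
    tools dichotomize ratios by maximally selected log-rank statistics
    and classify cases into the four PD-L1/CD8 tumor immune
    microenvironment quadrants, with contingency, rank-based and
    survival comparisons. A forward-model simulator generates
    ground-truthed synthetic slides and patient cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    jsonlite,
    png,
    tiff,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
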