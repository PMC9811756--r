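Package: gliovasc
Title: Quantification of Neuro- and Perivascular Inflammation in White Matter Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for quantifying microglial and astroglial
    inflammation in brightfield immunohistochemistry of periventricular white
    matter. Transfers MRI-drawn regions of interest (normal-appearing white
    matter and white matter hyperintensities) onto histology by landmark or
    intensity-based registration, separates H-DAB stains by optical-density
    colour deconvolution, segments IBA1-positive microglia and GFAP-positive
    astroglia, computes per-region morphometrics (frequency, area and
    intensity fractions, skeleton length, circularity), grades perivascular
    astrogliosis around detected vessel lumens on a 0-3 scale, and runs
    covariate-adjusted cohort statistics with Bonferroni correction. Includes
    a synthetic-cohort generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    car,
    stats,
    utils,
    grDevices
Suggests:
    lmerTest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
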