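Package: serumpanel
Title: Method-Comparison Statistics for Serum Mineral Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agreement analysis between a multi-element assay (ICP-MS) and
    routine clinical assays for serum mineral panels. Implements
    Passing-Bablok regression with rank-based confidence intervals and
    standardized-residual diagnostics, hemolysis-aware outlier filtering,
    relative-error Bland-Altman limits of agreement with bootstrap
    confidence intervals, robust descriptive statistics for non-Gaussian
    laboratory data (quartile coefficient of dispersion, quantile
    deviation, moment-based shape measures), and ROC/Youden screening of
    mineral surplus and deficiency against reference intervals. Ships a
    seeded synthetic-panel generator emulating the joint structure of
    paired serum measurements, including hemolysis interference and
    contamination outliers, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC
Config/testthat/edition: 3
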