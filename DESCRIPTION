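Package: gliomorph
Title: Nuclear Morphometry and Case-Level Classification for Astrocytic
    Tumor Histopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for digital pathology of common
    astrocytic tumors (diffuse astrocytoma, anaplastic astrocytoma,
    glioblastoma). Tiles annotated regions of interest into fixed-size
    patches with a margin-intersection filter, aggregates patch-level
    predictions into case-level diagnoses under inclusion criteria,
    quantifies cellularity and six nuclear morphological features (axis
    ratio, circularity, entropy, area, irregularity, perimeter) from
    instance label masks with four-moment summaries, compares groups with
    Welch's t-test (Bonferroni-corrected) and one-way ANOVA, and ranks
    features by bootstrap-weighted gradient-boosting importance. Includes a
    synthetic-data generator producing class-conditional nucleus images,
    ROI geometries and patch-prediction count tables with analytic ground
    truth, so the whole pipeline is testable without slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    tiff,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
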