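Package: ncrscreen
Title: Nuclear Translocation Reporter Screening and Functional Variant Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of nuclear translocation reporter assays used
    to annotate cancer variants functionally. Simulates ground-truthed
    two-channel fluorescence plate images (nuclear stain plus pathway
    reporter), segments cells and nuclei with Gaussian-mixture foreground
    detection and seeded cross-channel watershed, quantifies per-cell
    nuclear-to-cytoplasmic reporter ratios, converts condition-level ratios
    into normalized oncogenic-activity scores and drug-inhibition calls,
    applies patient-level survival-prediction rules, and compares
    progression-free survival between prediction groups with Kruskal-Wallis
    tests and Kaplan-Meier curves. Ships a 12-patient example cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    stats,
    mclust,
    EBImage,
    survival,
    generics,
    withr,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
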