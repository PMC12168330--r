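Package: plasmanet
Title: Plasma Proteome Co-Expression Networks and Biomarker Panels for
    Repetitive Head Injury Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for proximity-extension-assay plasma
    proteomics in cohorts with repetitive head impact exposure,
    Alzheimer's disease and controls: limit-of-detection and
    missingness quality control, Z-connectivity sample outlier removal,
    case-protected bootstrap covariate adjustment, signed weighted
    co-expression networks (biweight midcorrelation, topological
    overlap, dynamic hybrid module detection, eigenproteins and kME),
    differential abundance with Tukey-Kramer post hoc tests, Fisher
    exact gene-set enrichment, recursive-feature-elimination biomarker
    panels with a linear support vector machine, and module-trait
    association including neuropathology burden composites. Includes a
    synthetic-cohort generator with planted ground truth for testing
    every stage without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
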