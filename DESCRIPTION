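Package: frailomics
Title: Deficit-Accumulation Frailty Index Construction and Inflammation
    Association Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a deficit-accumulation frailty index (FI) from a cohort
    table and a declarative deficit schema (coding, screening by missingness,
    per-subject renormalisation over measured deficits, frailty cutoff), and
    runs the downstream inflammation analyses used in ageing cohort studies:
    biomarker transform policies with per-10-percent back-transformation of
    log-scale regression coefficients, Spearman correlations and group
    comparisons with automatic test selection, covariate-adjusted linear
    models, bulk PBMC expression preprocessing (quantile normalisation,
    max-IQR probe collapse), per-gene frailty exposure models with FDR
    control, cell-type deconvolution by constrained least squares, and
    monocyte marker-gene by biomarker association matrices. A
    synthetic-cohort generator with ground truth supports
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    limma,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
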