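Package: dyssync
Title: Mechanical Dyssynchrony Indices from Segmental Circumferential Strain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes left-ventricular mechanical dyssynchrony indices from
    segmental circumferential strain curves measured in a single mid-ventricular
    short-axis slice: the circumferential uniformity ratio estimate (CURE),
    derived from the spatial Fourier decomposition of strain across the six
    mid-ventricular AHA segments, and the systolic stretch index (SSI), the sum
    of lateral-wall systolic pre-stretch and septal rebound stretch. Includes a
    synthetic cohort generator emulating left bundle branch block (LBBB) versus
    normal-activation strain mechanics, and the statistical comparison
    machinery used to evaluate such indices: rank tests, univariable logistic
    odds ratios, ROC analysis with Youden cutoffs, stratified bootstrap
    comparison of paired AUCs, and intraclass correlation with standard error
    of measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse,
    rmarkdown,
    withr
Config/testthat/edition: 3
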