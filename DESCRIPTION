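Package: epidige
Title: Within-Patient 2D-DIGE Differential Proteomics of Epileptic Neocortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for within-patient differential
    analysis of two-dimensional difference gel electrophoresis (2D-DIGE)
    proteomics, built around a paired high- versus low-interictal-spiking
    neocortex design. Implements pooled-internal-standard (ratiometric) and
    total-volume normalization, dye-swap replicate averaging, per-patient
    fold-change screening, a nested cross-patient test on natural-log fold
    changes, spot-of-interest selection, Gower/Ward expression-pattern
    clustering with leave-one-out stability and marker-panel labelling,
    isoform roll-up statistics with exact small-sample Kendall correlation,
    and per-patient Fisher's-exact gene-set enrichment with cross-patient
    recurrence. Ships a synthetic-study generator with a ground-truth record
    so the whole pipeline is testable without access to raw gel images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    lmerTest,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
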