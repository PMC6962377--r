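Package: mechanomir
Title: Glioblastoma Cell Responses to Low Compressive Solid Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies glioblastoma cell responses to low compressive solid
    stress (13-115 Pa) from wound-healing assays, single-cell morphometrics,
    and transcriptome profiling. Provides wound-closure and matched-pair
    differential-closure statistics, decomposition of cell aspect-ratio
    distributions into one- or two-component shifted-lognormal mixtures with
    mode extraction and SSE/R-squared model selection, differential-expression
    threshold filtering, and a miRNA-mRNA pathway interaction analysis that
    scores each miRNA-pathway pair by intersection, percent overlap, and
    cumulative absolute fold change, classifies pathways into functional
    groups by keyword rules, and compares groups by ANOVA with Tukey-Kramer
    post hoc tests. A synthetic-data module emulates all required inputs
    (wound images, per-cell shape tables, expression tables, per-miRNA
    pathway/target exports) with known ground truth.
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
    stringr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    minpack.lm,
    EBImage,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
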