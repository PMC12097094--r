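Package: threedfunc
Title: Variant Effects on Three-Dimensional Genome Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating genetic variants to three-dimensional genome
    organization. Provides a flexible interaction-frequency statistic computed
    from multi-resolution Hi-C contact matrices with adaptive resolution and
    background extension; rule-based classifiers for disruptions of chromosome
    territories, A/B compartments, topologically associating domains (TADs)
    and chromatin loops; an expression-change statistic based on the one-sided
    Welch t CDF; and a two-phase variant-gene scoring algorithm (3DFunc) that
    fits an exponential decay between expression change and interaction-
    frequency change and ranks pairs by their residual from the fitted curve.
    Includes deterministic synthetic-data generators for Hi-C matrices,
    expression matrices and variant sets so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
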