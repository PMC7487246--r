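Package: topophen
Title: Flowering-Time Extension Across Topographic Aspects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies how paired north- and south-facing slopes extend the
    seasonal duration of flowering pollinator resources. Turns long-format
    weekly inflorescence surveys into cumulative flowering-proportion curves
    and 5/50/95% threshold dates, computes the combined-aspect flowering
    duration and the resource-extension statistic, decomposes extension into
    within-species and species-turnover components, summarises the
    microclimatic contrast between aspects (growing degree-days, seasonal
    means, soil moisture), and fits the supporting fixed-effects models with
    AICc and nested-F model comparison. A synthetic-landscape generator with
    calibrated aspect temperature offset and phenological sensitivity makes
    the whole pipeline reproducible and testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
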