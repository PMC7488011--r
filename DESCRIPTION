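Package: mirboot
Title: Bootstrap Stability Analysis of Circulating miRNA Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Iterative bootstrap resampling with replacement for qPCR
    panels of circulating microRNAs, designed for cohorts that must be
    disaggregated into small strata (for example by fetal sex).  Provides
    global-mean delta-Ct preprocessing of cycle-threshold matrices,
    significance-stability profiles for one-way ANOVA and gestational-age
    adjusted ANCOVA, Hedges' g effect sizes with bootstrap percentile
    confidence intervals, co-secretion correlation-network statistics with
    a bootstrap count-exceedance test, chromosome-pair enrichment of
    significantly correlated miRNA pairs, demographic cohort tests
    (Fisher's exact r x c, Kruskal-Wallis), and a synthetic cohort
    generator with planted group, sex-specific and latent-factor structure
    for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    withr
Config/testthat/edition: 3
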