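Package: gabasex
Title: Sex-Stratified Analysis of GABA-Related Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully simulated implementation of a cross-species
    analysis chain linking sex-related factors to expression of GABA-related
    genes (SST, GAD67, GAD65). Provides sex-stratified multi-study
    effect-size meta-analysis (Hedges' g, DerSimonian-Laird pooling, binary
    moderator meta-regression, weighted Stouffer Z-trend combination,
    percent-of-control summaries), seed-gene co-expression profiling and
    thresholded weighted network construction with core-module extraction,
    sex-stratified trans- and cis-eQTL mapping of X-chromosome variants with
    Benjamini-Hochberg correction and LD-block collapsing, and 2x2x2
    factorial (genetic sex x gonadal sex x hormone) analysis of behavioral
    and expression endpoints with Type III sums of squares and Tukey
    contrasts. A synthetic-data module generates every input with planted,
    recoverable effects so the whole chain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    emmeans,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
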