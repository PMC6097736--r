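Package: sldsr
Title: Stratified LD Score Regression with Tissue-Specific eQTL Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how tissue-specific and tissue-shared cis-eQTLs are
    enriched in their genome-wide effects on complex traits. Provides a
    synthetic-data generator with known ground truth (LD-blocked reference
    panels, two-tissue eQTL catalogs with tunable cross-tissue effect
    correlation, GWAS chi-square summary statistics under a partitioned
    polygenic model, histone-mark interval sets and differential-expression
    rankings), stratified LD score computation, eQTL annotation construction,
    broad and narrow tissue-sharedness classification, stratified LD score
    regression with partitioned heritability, enrichment ratios and block
    jackknife standard errors, inverse-variance weighted cross-trait
    meta-analysis, and a declarative pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
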