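Package: riboase
Title: Genetic Influences on Translation from Allele-Specific Ribosome
    Profiling Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genetic influences on translation from paired mRNA and
    ribosome-footprint count data for two yeast strains and their diploid
    hybrid. Implements power-equalizing count resampling (library downsampling
    and per-gene hypergeometric equalization), exact binomial and G-tests for
    differential mRNA, footprint and translational-efficiency (TE) expression
    with Bonferroni and Storey q-value correction, major-axis and standardized
    major-axis slope estimation with bootstrap confidence intervals for
    cis/trans decomposition, classification of TE-significant genes into
    directional categories with chi-squared ratio tests, SNP-site bias
    filtering for unbiased allele-specific quantification, and comparison of
    expression differences to protein-QTL effects. A negative-binomial count
    simulator with known cis, trans and TE effects makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
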