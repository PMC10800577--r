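Package: giscan
Title: Gene-Based Epistasis Scanning and Genetic-Interaction Networks for
    Case-Control GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline from case-control genotypes to a
    direction-signed gene-gene genetic-interaction (GI) network. Implements
    case-control quality control (exact Hardy-Weinberg tests with
    stratum-specific tiers, missingness and MAF filters, PI-HAT
    relatedness exclusion on an LD-pruned variant panel), a two-stage
    SNP-pair interaction scan (a fast Kirkwood-superposition log-linear
    screening statistic followed by a logistic-regression interaction test
    with odds ratios), SNP-to-gene assignment over gene bodies and
    promoters, collapse of SNP-pair results to gene-pair interactions by
    best p-value, Bonferroni and Benjamini-Hochberg control over the
    gene-pair test universe, and hub-gene degree summaries. Includes a
    synthetic cohort generator with planted epistatic architecture so
    every stage is testable without external data, plus PLINK bed/bim/fam
    and BED annotation readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
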