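Package: corefun
Title: Core Functional Gene Analysis for Multi-Sample Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identifies core functional genes in gene-family-by-sample
    metagenome profiles by the stability of their within-sample abundance
    ranks, and tests functional-ontology categories for enrichment in core
    genes against a permutation null with Benjamini-Hochberg false
    discovery rate control.  Also summarizes nitrogen-cycle gene
    abundances (with denitrification branch subtotals), glycoside
    hydrolase family fractions from top-hit tables, and screens
    taxon-by-metadata Spearman correlation matrices with an
    absolute-correlation retention filter.  A synthetic-profile generator
    with planted ground truth supports end-to-end validation of the
    pipeline without access to raw sequence data.
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
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
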