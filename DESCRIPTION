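Package: triofunnel
Title: Rare-Variant Prioritisation for Trio and Dyad Exome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for prioritising rare coding variants
    in case-parent trios and case-mother dyads ascertained for syndromic
    craniofacial and limb malformations. Implements a staged filtering
    funnel (protein-altering consequence classes, minor allele frequency
    below a rarity threshold across three population databases, a
    majority vote over eleven in-silico pathogenicity predictors, CADD
    and SpliceAI gates for loss-of-function and splice-region variants),
    Mendelian inheritance classification including de novo, dominant with
    incomplete penetrance, recessive, compound-heterozygous and
    missing-parent handling, hub-gene ranking on thresholded
    protein-interaction networks by maximal clique centrality, and
    hypergeometric over-representation analysis of the prioritised gene
    list with Benjamini-Hochberg correction. A cohort simulator with
    planted inheritance patterns provides ground truth for end-to-end
    validation without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
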