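Package: nlrforge
Title: Annotation and Evolutionary Analysis of Plant NLR Resistance Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for annotating nucleotide-binding
    leucine-rich-repeat (NLR) disease-resistance genes from transcriptome
    and genome assemblies and for analysing their evolution. Detection
    combines de novo motif elicitation (EM over an OOPS model) with
    MAST-style scanning, a profile hidden Markov model of the NB-ARC
    domain, and an iterative PSSM homology search; candidate proteins are
    classified into the CNL/TNL/RNL domain-architecture taxonomy; gene
    clusters are called on ordered genome annotations under the
    gap-of-at-most-8 rule with chi-square tests of chromosomal
    distribution. Evolutionary analyses cover NB-domain phylogenies
    (JTT maximum-likelihood distances, neighbor joining, bootstrap
    support, outgroup rerooting, clade collapsing), SLAC-style per-codon
    selection analysis, composite-likelihood nucleotide divergence, and
    birth-death modelling of gene family size change along a dated
    species tree. Seeded synthetic-data generators with known ground
    truth support every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    phangorn,
    purrr,
    Rcpp,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
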