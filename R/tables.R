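# Bundled published survey tables for the Cucurbita NLR repertoire:
# per-accession expressed-NLR counts for 40 transcriptomes, domain-class
# complements of 5 genome assemblies, and cluster compositions of 4
# genomes. These printed counts are inputs the summary machinery can
# reproduce table arithmetic from; no sequence data is bundled.

read_bundled_tsv <- function(name) {
  path <- system.file("extdata", name, package = "nlrforge", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Published Cucurbita expressed-NLR repertoire counts
#'
#' Per-accession counts of expressed NLR genes annotated from 40
#' Cucurbita transcriptomes (12 species, 6 geographic regions).
#'
#' @return Tibble: `species`, `accession`, `origin`, `n_enlr`.
#' @export
cucurbita_repertoire <- function() read_bundled_tsv("cucurbita_enlr_repertoire.tsv")

#' Published Cucurbita NLR domain-class complements
#'
#' Per-species counts of full-length (CNL/TNL/RNL) and partial
#' architecture classes for 5 Cucurbita genome assemblies.
#'
#' @return Tibble: `class_label`, `is_full_length`, one count column per
#'   species.
#' @export
cucurbita_domain_classes <- function() read_bundled_tsv("cucurbita_nlr_classes.tsv")

#' Published Cucurbita NLR cluster compositions
#'
#' Singleton/pair/triplet/cluster compositions of 4 fully assembled
#' Cucurbita genomes under the gap-of-at-most-8 clustering rule
#' (`cluster_genes` is the total gene count inside clusters of size 4+).
#'
#' @return Tibble: `species`, `singletons`, `pairs`, `triplets`,
#'   `clusters`, `cluster_genes`, `total_nlrs`.
#' @export
cucurbita_cluster_compositions <- function() read_bundled_tsv("cucurbita_nlr_clusters.tsv")
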