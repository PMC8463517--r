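# Gene-cluster calling under the gap-of-at-most-8 rule and chromosomal
# distribution statistics.

#' Call NLR gene clusters on ordered genome annotations
#'
#' Genes on each chromosome are scanned in start order; maximal runs of
#' NLR genes in which each adjacent NLR pair is separated by no more than
#' `max_gap` intervening non-NLR genes form one call (the Richly
#' clustering rule). Strand is ignored; gaps are counted in genes, not
#' base pairs. Calls of size 1/2/3 are singletons/pairs/triplets; size 4
#' and up is a cluster.
#'
#' @param loci Tibble of gene loci (`gene_id`, `chromosome`, `start`,
#'   `end`, `is_nlr`), e.g. from [read_gff3()].
#' @param max_gap Maximum intervening non-NLR genes within a call
#'   (default 8).
#' @return Tibble with one row per call: `chromosome`, `cluster_id`,
#'   `category`, `n_members`, `members` (list-column of NLR gene ids in
#'   positional order).
#' @export
call_clusters <- function(loci, max_gap = 8) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end", "is_nlr") %in% names(loci)))
  if (anyDuplicated(loci[, c("chromosome", "start", "end")])) {
    stop("duplicate gene coordinates")
  }
  loci <- dplyr::arrange(loci, .data$chromosome, .data$start)
  calls <- loci %>%
    dplyr::group_by(.data$chromosome) %>%
    dplyr::group_map(function(df, key) {
      idx <- which(df$is_nlr)
      if (!length(idx)) return(NULL)
      # new run whenever > max_gap non-NLR genes intervene
      brk <- c(0L, cumsum(diff(idx) - 1L > max_gap))
      purrr::map_dfr(split(idx, brk), function(run) {
        tibble::tibble(chromosome = key$chromosome[[1]],
                       n_members = length(run),
                       members = list(df$gene_id[run]))
      })
    }) %>%
    dplyr::bind_rows()
  if (is.null(calls) || nrow(calls) == 0L) {
    return(tibble::tibble(chromosome = character(), cluster_id = character(),
                          category = character(), n_members = integer(),
                          members = list()))
  }
  calls %>%
    dplyr::mutate(cluster_id = paste0("call_", dplyr::row_number()),
                  category = dplyr::case_when(
                    .data$n_members == 1L ~ "singleton",
                    .data$n_members == 2L ~ "pair",
                    .data$n_members == 3L ~ "triplet",
                    TRUE ~ "cluster")) %>%
    dplyr::select("chromosome", "cluster_id", "category", "n_members", "members")
}

#' Build a cluster-call table from a published composition
#'
#' Convenience constructor used when only the tabulated composition of a
#' genome is available (counts of singletons, pairs and triplets plus the
#' individual cluster sizes), so that [summarize_clusters()] can
#' reproduce a printed table row.
#'
#' @param singletons,pairs,triplets Counts of calls of size 1, 2, 3.
#' @param cluster_sizes Integer vector of sizes (each >= 4) of the
#'   clusters.
#' @return Tibble in the [call_clusters()] layout (anonymous members).
#' @export
cluster_calls_from_composition <- function(singletons = 0, pairs = 0,
                                           triplets = 0,
                                           cluster_sizes = integer()) {
  stopifnot(all(cluster_sizes >= 4))
  sizes <- c(rep(1L, singletons), rep(2L, pairs), rep(3L, triplets),
             as.integer(cluster_sizes))
  tibble::tibble(
    chromosome = "chrU",
    cluster_id = paste0("call_", seq_along(sizes)),
    category = dplyr::case_when(sizes == 1L ~ "singleton",
                                sizes == 2L ~ "pair",
                                sizes == 3L ~ "triplet",
                                TRUE ~ "cluster"),
    n_members = sizes,
    members = purrr::map(sizes, ~ paste0("g", seq_len(.x))))
}

#' Summarise cluster calls in the published table layout
#'
#' @param calls Tibble from [call_clusters()] (or
#'   [cluster_calls_from_composition()]).
#' @param total_nlrs Total NLR genes in the genome (must be at least the
#'   number of grouped genes).
#' @return One-row tibble: `singletons`, `pairs`, `triplets`, `clusters`,
#'   `mean_cluster_size` (over calls of size >= 4; NA when none),
#'   `grouped` (genes in pairs, triplets or clusters) and
#'   `grouped_percent` (rounded half-up).
#' @export
summarize_clusters <- function(calls, total_nlrs) {
  grouped <- sum(calls$n_members[calls$category != "singleton"])
  if (total_nlrs < grouped) stop("total_nlrs smaller than grouped gene count")
  cl <- calls$n_members[calls$category == "cluster"]
  tibble::tibble(
    singletons = sum(calls$category == "singleton"),
    pairs = sum(calls$category == "pair"),
    triplets = sum(calls$category == "triplet"),
    clusters = length(cl),
    mean_cluster_size = if (length(cl)) mean(cl) else NA_real_,
    grouped = grouped,
    grouped_percent = if (total_nlrs > 0) round_half_up(100 * grouped / total_nlrs)
                      else NA_real_)
}

#' Chi-square test of NLR counts against chromosome size
#'
#' Tests whether NLR genes are distributed across chromosomes in
#' proportion to chromosome length: expected counts are
#' total * length_i / sum(length), the statistic is the usual
#' sum((obs - exp)^2 / exp) with k - 1 degrees of freedom
#' (delegated to [stats::chisq.test()]).
#'
#' @param nlr_counts Integer vector of NLR counts per chromosome.
#' @param chromosome_lengths Lengths (bp, or gene counts if preferred) of
#'   the same chromosomes; all positive.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
chromosome_chisq <- function(nlr_counts, chromosome_lengths) {
  stopifnot(length(nlr_counts) == length(chromosome_lengths))
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  p <- chromosome_lengths / sum(chromosome_lengths)
  if (any(sum(nlr_counts) * p == 0)) stop("zero expected count")
  ht <- suppressWarnings(stats::chisq.test(nlr_counts, p = p))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}
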