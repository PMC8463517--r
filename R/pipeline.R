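# End-to-end orchestration on synthetic inputs: detection cascade,
# classification, cluster genomics, phylogeny, selection, family
# dynamics and qPCR summaries, persisted as TSV/newick reports.

#' Default pipeline configuration
#'
#' One declarative list holding every stage parameter at its package
#' default; unknown keys passed to [run_pipeline()] are rejected. All
#' randomness flows from the single `seed`.
#'
#' @return Named list of parameters.
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    # synthetic inputs
    n_transcripts = 60, nlr_fraction = 0.25, short_fraction = 0.7,
    chromosomes = c(chr1 = 5e6, chr2 = 4e6),
    n_genes = 120,
    cluster_spec = list(singletons = 4, pairs = 2, triplets = 1,
                        cluster_sizes = 4),
    # detection
    n_motifs = 3, motif_width = 12, motif_evalue = 1e-3,
    hmm_bits_threshold = 10,
    psiblast_evalue = 1e-10, psiblast_max_iter = 2,
    # phylogeny
    bootstrap_n = 20, collapse_support = 80, min_domain_coverage = 0.5,
    # selection
    selection_omega = 0.2, selection_codons = 120, min_site_coverage = 0.8,
    slac_alpha = 0.1,
    # family dynamics
    lambda = 0.01397, n_families = 40, bdp_max_count = 40, n_sim = 50,
    # qpcr
    qpcr_samples = 3
  )
}

#' Run the full pipeline on synthetic inputs
#'
#' Executes the annotation cascade (six-frame translation, motif scan,
#' profile-HMM scan, iterative PSSM search, union), classification and
#' repertoire summary, cluster calling with the chromosome chi-square
#' test, an NB-domain bootstrap phylogeny, SLAC selection analysis on a
#' simulated codon alignment, birth-death family dynamics and a qPCR
#' expression table, writing every report into `out_dir`. Reports are a
#' pure function of the configuration (including its seed).
#'
#' @param config Configuration list; see [default_pipeline_config()].
#'   Only keys present in the defaults are accepted.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the main in-memory results and the
#'   paths of the written reports.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("nlrforge_run")) {
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log")
  logline <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("config: ", paste(names(cfg), vapply(cfg, function(x)
    paste(format(unlist(x)), collapse = ","), character(1)),
    sep = "=", collapse = "; "))
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- inputs -------------------------------------------------------------
  tx <- stage("simulate", gen_transcriptome(
    cfg$n_transcripts, cfg$nlr_fraction, cfg$short_fraction, seed = cfg$seed))
  truth <- attr(tx, "truth")
  layout <- stage("simulate", gen_genome_layout(
    cfg$chromosomes, cfg$n_genes, cfg$cluster_spec, seed = cfg$seed + 1))
  profiles <- stage("simulate", synthetic_domain_profiles(seed = cfg$seed + 2))
  refset <- stage("simulate", gen_reference_nb_set(seed = cfg$seed + 3))

  # --- detection ----------------------------------------------------------
  frames <- stage("detect", six_frame_translate(tx))
  motifs <- stage("detect", elicit_motifs(refset, n_motifs = cfg$n_motifs,
                                          width = cfg$motif_width,
                                          seed = cfg$seed + 4))
  motif_hits_tbl <- stage("detect",
                          scan_motifs(frames, motifs,
                                      evalue_threshold = cfg$motif_evalue))
  # best peptide per transcript (longest frame translation, for HMM and
  # downstream classification)
  best_frames <- frames %>%
    dplyr::mutate(aa = nchar(gsub("[*X]", "", .data$peptide))) %>%
    dplyr::group_by(.data$source_id) %>%
    dplyr::slice_max(.data$aa, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  prots <- tibble::tibble(id = best_frames$source_id,
                          residues = best_frames$peptide)
  hmm_scores <- stage("detect", score_profile_hmm(profiles$nb, prots))
  hmm_hits_tbl <- tibble::tibble(seq_id = prots$id, stage = "hmm",
                                 score_bits = hmm_scores,
                                 e_value = NA_real_) %>%
    dplyr::filter(.data$score_bits >= cfg$hmm_bits_threshold)
  logline("hmm threshold bits: ", cfg$hmm_bits_threshold)
  seed_ids <- unique(c(motif_hits_tbl$seq_id, hmm_hits_tbl$seq_id))
  iter_hits_tbl <- NULL
  if (length(seed_ids)) {
    queries <- dplyr::slice_head(
      dplyr::filter(prots, .data$id %in% seed_ids), n = 3)
    iter_hits_tbl <- stage("detect", iterative_pssm_search(
      queries, prots, evalue_cutoff = cfg$psiblast_evalue,
      max_iter = cfg$psiblast_max_iter))
  }
  hits <- combine_detection_hits(motif_hits_tbl, hmm_hits_tbl, iter_hits_tbl)
  paths$hits <- file.path(out_dir, "detection_hits.tsv")
  utils::write.table(dplyr::select(hits, dplyr::any_of(
    c("seq_id", "stage", "score_bits", "e_value"))),
    paths$hits, sep = "\t", row.names = FALSE, quote = FALSE)

  # --- classification -----------------------------------------------------
  cand <- dplyr::filter(prots, .data$id %in% unique(hits$seq_id))
  records <- stage("classify", annotate_nlrs(
    cand, nb_profile = profiles$nb, nterm_profiles = profiles$nterm,
    bits_threshold = cfg$hmm_bits_threshold))
  repertoire <- summarize_repertoire(
    records, transcript_lengths = nchar(tx$residues[tx$id %in% records$gene_id]))
  paths$records <- file.path(out_dir, "nlr_records.tsv")
  utils::write.table(dplyr::select(records, -"domains"), paths$records,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  paths$repertoire <- file.path(out_dir, "repertoire_summary.tsv")
  utils::write.table(glance(repertoire), paths$repertoire, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- cluster genomics ---------------------------------------------------
  calls <- stage("cluster", call_clusters(layout))
  csum <- summarize_clusters(calls, total_nlrs = sum(layout$is_nlr))
  counts <- layout %>% dplyr::group_by(.data$chromosome) %>%
    dplyr::summarise(n = sum(.data$is_nlr), .groups = "drop")
  chisq <- chromosome_chisq(counts$n, cfg$chromosomes[counts$chromosome])
  paths$clusters <- file.path(out_dir, "cluster_summary.tsv")
  utils::write.table(dplyr::bind_cols(csum, chisq), paths$clusters,
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # --- phylogeny on detected NB regions ------------------------------------
  nb_seqs <- records %>%
    dplyr::mutate(nb = purrr::map2_chr(.data$domains, .data$gene_id, function(d, g) {
      row <- d[d$kind == "NB", ]
      if (!nrow(row)) return(NA_character_)
      prot <- cand$residues[cand$id == g]
      substr(prot, row$start[1] + 1, row$end[1])
    })) %>%
    dplyr::filter(!is.na(.data$nb)) %>%
    dplyr::transmute(id = .data$gene_id, residues = .data$nb)
  tree_path <- NULL
  if (nrow(nb_seqs) >= 4) {
    nb_len <- nchar(synthetic_domain_consensus()$NB)
    kept <- stage("phylo", filter_by_domain_coverage(
      nb_seqs, nb_len, cfg$min_domain_coverage))
    kept <- dplyr::distinct(kept, .data$id, .keep_all = TRUE)
    if (nrow(kept) >= 4) {
      msa <- stage("phylo", progressive_align(kept))
      btree <- stage("phylo", bootstrap_support(msa, n = cfg$bootstrap_n,
                                                seed = cfg$seed + 5))
      ctree <- stage("phylo", collapse_clades(btree, cfg$collapse_support))
      tree_path <- file.path(out_dir, "nb_tree.nwk")
      ape::write.tree(ctree, tree_path)
      paths$tree <- tree_path
    }
  }

  # --- selection ----------------------------------------------------------
  sel_tree <- ape::read.tree(text = "((s1:0.2,s2:0.2):0.1,(s3:0.2,s4:0.2):0.1);")
  cds_aln <- stage("selection", simulate_codon_evolution(
    sel_tree, omega = cfg$selection_omega, n_codons = cfg$selection_codons,
    seed = cfg$seed + 6))
  cds_aln <- filter_sites(cds_aln, cfg$min_site_coverage)
  sl <- stage("selection", slac(cds_aln, sel_tree, alpha = cfg$slac_alpha))
  pi_hat <- stage("selection", mcl_divergence(cds_aln))
  paths$selection <- file.path(out_dir, "selection_sites.tsv")
  utils::write.table(tidy(sl), paths$selection, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths$selection_summary <- file.path(out_dir, "selection_summary.tsv")
  utils::write.table(dplyr::mutate(glance(sl), pi = as.numeric(pi_hat)),
                     paths$selection_summary, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- family dynamics ----------------------------------------------------
  sp_tree <- ape::read.tree(
    text = "((a:5,b:5):5,(c:7,(d:4,e:4):3):3);")
  fams <- stage("cafe", simulate_bdp_families(
    sp_tree, cfg$lambda, cfg$n_families, seed = cfg$seed + 7))
  bc <- stage("cafe", branch_changes(fams, sp_tree, cfg$lambda,
                                     max_count = cfg$bdp_max_count))
  rf <- stage("cafe", rapid_families(fams, sp_tree, cfg$lambda,
                                     n_sim = cfg$n_sim, seed = cfg$seed + 8,
                                     max_count = cfg$bdp_max_count))
  paths$families <- file.path(out_dir, "family_dynamics.tsv")
  utils::write.table(dplyr::left_join(rf, bc$root_states, by = "family_id"),
                     paths$families, sep = "\t", row.names = FALSE, quote = FALSE)
  paths$expansion <- file.path(out_dir, "average_expansion.tsv")
  utils::write.table(bc$average_expansion, paths$expansion, sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- qpcr ---------------------------------------------------------------
  ctab <- stage("qpcr", gen_ct_table(n_samples = cfg$qpcr_samples,
                                     seed = cfg$seed + 9))
  expr <- stage("qpcr", relative_expression(ctab))
  paths$qpcr <- file.path(out_dir, "qpcr_expression.tsv")
  utils::write.table(expr, paths$qpcr, sep = "\t", row.names = FALSE,
                     quote = FALSE)

  logline("stages completed: detect, classify, cluster, phylo, selection, ",
          "cafe, qpcr")
  invisible(list(config = cfg, hits = hits, records = records,
                 repertoire = repertoire, truth = truth,
                 cluster_summary = csum, chisq = chisq, slac = sl,
                 pi = as.numeric(pi_hat), bdp = bc, rapid = rf,
                 qpcr = expr, paths = paths, out_dir = out_dir))
}
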