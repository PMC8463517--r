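# Seeded synthetic-data generators with known ground truth. All
# sequences here are synthetic stand-ins for real reference sets: domain
# "consensus" strings are fixed constants carrying the structural
# signatures the detectors look for (P-loop/kinase-2/GLPL-like words in
# the NB stand-in, heptad repeats for CC, exact LxxLxL repeats for LRR),
# not sequences from any database.

POLAR_FILL <- c("S", "T", "N", "Q", "D", "E", "G", "P", "K", "R", "H")

#' Synthetic domain consensus sequences
#'
#' Fixed stand-in consensus strings for the domains the pipeline
#' detects. The NB stand-in carries P-loop-, kinase-2- and GLPL-like
#' motif words; CC is a perfect heptad repeat (hydrophobic a/d
#' positions); LRR is an exact LxxLxL repeat; the seven integrated
#' -domain stand-ins are arbitrary distinct sequences.
#'
#' @return Named list: `NB`, `TIR`, `RPW8`, `CC`, `LRR`, and `IDs` (a
#'   named list of 7 integrated-domain stand-ins).
#' @export
synthetic_domain_consensus <- function() {
  nb <- paste0("SDDREKSTNG", "GMGGLGKTTL", "ARQESTDNKE",
               "KRYLIVLDDV", "WDTSQWEGNK", "RSGSRIIITT",
               "RDESTVAKHG", "STPYELKQLS", "EGLPLALKVW",
               "GDRSQNEWKR", "MHDLVRDMSE", "NKGTDEKQSR")
  tir <- paste0("YDVFLSFRGE", "DTRKGFTSHL", "EKALSDAGIN",
                "TFRDDKELRK", "GESISPELLR", "AIEESRVSIV",
                "VFSKNYASST", "WCLDELVKIM", "ECRKTKGQIV")
  rpw8 <- paste0("WEDAGKQVGE", "AIKPILEQLS", "GRASQYLEDK",
                 "VGRELNYKSN", "LEDLKDTLEK", "SDRKGSENQD")
  cc <- strrep("LQELADKLQE", 4)          # heptad-periodic hydrophobic a/d
  lrr <- strrep("LSGLSSLTTLDLSNNQLSGP", 5)
  ids <- list(
    hydrolase = paste0("HEDTGKNSRQ", "DHGETKNSDR", "EQHGDSTNKR",
                       "GHDETSQNKD", "RHGETDSNQK", "EHDGTSKNRQ"),
    snare = paste0("QNEDKRSTLE", "DRNQESTKGE", "NQDERSKTGD",
                   "RNEQDSTKEG", "QDNERKSTGE", "NRDQESKTGD"),
    cytb5 = paste0("HGEDYKTSNR", "YHGDEKTSRN", "GHYEDKSTNR",
                   "HYGEDTKSNR", "YGHDETKSRN", "HGYDEKTSNR"),
    pmei = paste0("STDKGENQRP", "TSKDGQENRP", "DSTKGENQPR",
                  "KTSDGENQRP", "SDTKGQENPR", "TKSDGENQRP"),
    pex = paste0("CKDESGTNRQ", "KCDSEGTNQR", "DCKESGTNRQ",
                 "CDKSEGTNQR", "KDCESGTNRQ", "CKDSEGTNQR"),
    kinase = paste0("GEGSTGKQDR", "EGSGTKQDRN", "GSEGTKQDNR",
                    "SGEGTKQDRN", "EGSGKTQDNR", "GESGTKQDRN"),
    zinc_finger = paste0("CEHCGKSFSR", "HCECGKSFRS", "ECHCGKSFSR",
                         "CHECGKSFRS", "HECCGKSFSR", "CEHCGKSFRS"))
  list(NB = nb, TIR = tir, RPW8 = rpw8, CC = cc, LRR = lrr, IDs = ids)
}

# point-mutate a protein string at the given per-site rate
mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  ch[hit] <- sample(AA20, sum(hit), replace = TRUE)
  paste(ch, collapse = "")
}

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference NB-domain set
#'
#' `n` protein sequences over a uniform random background, each carrying
#' the planted motifs (in order, at random non-overlapping offsets).
#' Stands in for a curated reference NB-ARC domain collection when
#' exercising motif elicitation and scanning.
#'
#' @param n Number of sequences (default 30).
#' @param length Sequence length (default 120).
#' @param motif_spec Character vector of planted motifs (default: three
#'   12-mers drawn from the synthetic NB consensus).
#' @param seed Seed.
#' @param mutation_rate Per-site substitution rate applied to each
#'   planted motif occurrence (default 0, exactly conserved).
#' @return Sequence tibble (`id`, `alphabet`, `residues`) with the
#'   planted occurrences in `attr(, "truth")` (`id`, `motif`, `start`
#'   0-based).
#' @export
gen_reference_nb_set <- function(n = 30, length = 120,
                                 motif_spec = NULL, seed = 1,
                                 mutation_rate = 0) {
  set.seed(seed)
  if (is.null(motif_spec)) {
    nb <- synthetic_domain_consensus()$NB
    motif_spec <- c(substr(nb, 11, 22), substr(nb, 31, 42), substr(nb, 81, 92))
  }
  w <- nchar(motif_spec)
  if (sum(w) + 2 * length(motif_spec) > length) stop("motifs do not fit")
  truth <- list()
  seqs <- vapply(seq_len(n), function(i) {
    bg <- strsplit(random_protein(length), "")[[1]]
    # random ordered non-overlapping offsets with at least 1 spacer
    free <- length - sum(w)
    cuts <- sort(sample.int(free - length(w), length(w)))
    starts <- cuts + c(0, cumsum(w))[seq_along(w)]
    for (k in seq_along(motif_spec)) {
      mot <- mutate_protein(motif_spec[k], mutation_rate)
      bg[(starts[k] + 1):(starts[k] + w[k])] <- strsplit(mot, "")[[1]]
      truth[[length(truth) + 1L]] <<-
        tibble::tibble(id = paste0("ref", i), motif = motif_spec[k],
                       start = starts[k])
    }
    paste(bg, collapse = "")
  }, character(1))
  out <- tibble::tibble(id = paste0("ref", seq_len(n)), alphabet = "protein",
                        residues = seqs)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

#' Profile HMMs for the synthetic domain library
#'
#' Builds one profile HMM per synthetic domain stand-in (NB, TIR, RPW8
#' and the 7 integrated domains) from `n_train` mutated copies of each
#' consensus. Used by tests and the bundled pipeline fixture.
#'
#' @param seed Seed for the training copies.
#' @param n_train Training sequences per domain (default 10).
#' @param mutation_rate Per-site substitution rate (default 0.05).
#' @return List: `nb` (an `nlr_phmm`) and `nterm` (named list of
#'   `nlr_phmm`s for TIR, RPW8 and the integrated domains).
#' @export
synthetic_domain_profiles <- function(seed = 1, n_train = 10,
                                      mutation_rate = 0.05) {
  set.seed(seed)
  cons <- synthetic_domain_consensus()
  train_hmm <- function(consensus) {
    msa <- tibble::tibble(
      id = paste0("t", seq_len(n_train)),
      aligned = vapply(seq_len(n_train),
                       function(i) mutate_protein(consensus, mutation_rate),
                       character(1)))
    build_profile_hmm(msa)
  }
  nterm <- c(list(TIR = train_hmm(cons$TIR), RPW8 = train_hmm(cons$RPW8)),
             lapply(cons$IDs, train_hmm))
  list(nb = train_hmm(cons$NB), nterm = nterm)
}

# back-translate a protein to a CDS with uniformly random synonymous codons
protein_to_cds <- function(prot) {
  ct <- codon_tables()
  by_aa <- split(ct$sense, ct$aa[ct$sense])
  ch <- strsplit(prot, "")[[1]]
  paste(vapply(ch, function(a) {
    opts <- by_aa[[a]]
    if (is.null(opts)) opts <- ct$sense
    sample(opts, 1)
  }, character(1)), collapse = "")
}

#' Generate a synthetic fragmented transcriptome
#'
#' Emulates a de novo assembled transcriptome: a fraction `nlr_fraction`
#' of transcripts encode planted NLR architectures (CNL/TNL/RNL built
#' from the synthetic domain library with polar linkers), and a fraction
#' `short_fraction` of the NLR transcripts are fragmented to under
#' 700 bp, truncating the encoded architecture the way short assembly
#' fragments do. Remaining transcripts encode random proteins.
#'
#' @param n Number of transcripts.
#' @param nlr_fraction Fraction of transcripts carrying an NLR
#'   architecture (default 0.1).
#' @param short_fraction Fraction of NLR transcripts fragmented below
#'   700 bp (default 0.7).
#' @param seed Seed.
#' @param mutation_rate Per-site substitution rate on planted domains
#'   (default 0.03).
#' @return DNA tibble (`id`, `alphabet`, `residues`) with
#'   `attr(, "truth")`: `id`, `is_nlr`, `class_label` (label implied by
#'   the retained planted domains), `is_short`, `protein`.
#' @export
gen_transcriptome <- function(n, nlr_fraction = 0.1, short_fraction = 0.7,
                              seed = 1, mutation_rate = 0.03) {
  set.seed(seed)
  cons <- synthetic_domain_consensus()
  linker <- function() random_protein(sample(10:20, 1), POLAR_FILL)

  make_nlr <- function() {
    cls <- sample(c("CNL", "TNL", "RNL"), 1, prob = c(0.4, 0.35, 0.25))
    nterm <- switch(cls, CNL = cons$CC, TNL = cons$TIR, RNL = cons$RPW8)
    nterm_kind <- switch(cls, CNL = "CC", TNL = "TIR", RNL = "RPW8")
    parts <- c(nterm, cons$NB, cons$LRR)
    kinds <- c(nterm_kind, "NB", "LRR")
    parts <- vapply(parts, mutate_protein, character(1), rate = mutation_rate)
    segs <- character(0); seg_kind <- character(0)
    for (k in seq_along(parts)) {
      segs <- c(segs, linker(), parts[k])
      seg_kind <- c(seg_kind, NA, kinds[k])
    }
    segs <- c(segs, linker()); seg_kind <- c(seg_kind, NA)
    list(protein = paste(segs, collapse = ""), segs = segs, kinds = seg_kind)
  }

  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("tx%04d", i)
    is_nlr <- stats::runif(1) < nlr_fraction
    if (is_nlr) {
      arch <- make_nlr()
      is_short <- stats::runif(1) < short_fraction
      segs <- arch$segs; kinds <- arch$kinds
      if (is_short) {
        # keep a suffix or prefix of segments fitting in < 700 bp (~230 aa)
        max_aa <- floor(sample(450:690, 1) / 3)
        from_start <- stats::runif(1) < 0.5
        if (!from_start) { segs <- rev(segs); kinds <- rev(kinds) }
        keep <- cumsum(nchar(segs)) <= max_aa
        # always keep at least one domain segment
        if (!any(keep & !is.na(kinds))) {
          keep[which(!is.na(kinds))[1]] <- TRUE
          keep[seq_len(which(!is.na(kinds))[1])] <- TRUE
        }
        segs <- segs[keep]; kinds <- kinds[keep]
        if (!from_start) { segs <- rev(segs); kinds <- rev(kinds) }
      }
      protein <- paste(segs, collapse = "")
      label <- classify_architecture(stats::na.omit(kinds))$class_label
      cds <- protein_to_cds(protein)
      rows[[i]] <- tibble::tibble(id = id, alphabet = "dna", residues = cds)
      truth[[i]] <- tibble::tibble(id = id, is_nlr = TRUE, class_label = label,
                                   is_short = nchar(cds) < 700,
                                   protein = protein)
    } else {
      prot <- random_protein(sample(80:450, 1))
      cds <- protein_to_cds(prot)
      rows[[i]] <- tibble::tibble(id = id, alphabet = "dna", residues = cds)
      truth[[i]] <- tibble::tibble(id = id, is_nlr = FALSE,
                                   class_label = "none",
                                   is_short = nchar(cds) < 700, protein = prot)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

#' Generate a synthetic genome layout with planted NLR clusters
#'
#' Lays out genes along chromosomes and plants NLR groups (singletons,
#' pairs, triplets, larger clusters) with intra-group gaps of at most 8
#' intervening non-NLR genes and inter-group gaps of at least
#' `min_between` (default 9), so the Richly-rule caller should recover
#' the planted composition exactly.
#'
#' @param chromosomes Named numeric vector of chromosome lengths (bp).
#' @param n_genes Total genes to place (at least the planted demand).
#' @param cluster_spec List with `singletons`, `pairs`, `triplets`
#'   counts and `cluster_sizes` (integer vector, each >= 4).
#' @param seed Seed.
#' @param min_between Minimum non-NLR genes between planted groups.
#' @return Locus tibble (as [read_gff3()]) with `attr(, "truth")`: the
#'   planted composition.
#' @export
gen_genome_layout <- function(chromosomes, n_genes, cluster_spec, seed = 1,
                              min_between = 9) {
  set.seed(seed)
  spec <- utils::modifyList(list(singletons = 0, pairs = 0, triplets = 0,
                                 cluster_sizes = integer()), cluster_spec)
  group_sizes <- c(rep(1L, spec$singletons), rep(2L, spec$pairs),
                   rep(3L, spec$triplets), as.integer(spec$cluster_sizes))
  group_sizes <- sample(group_sizes)  # shuffle placement order
  n_nlr <- sum(group_sizes)

  # build the gene-by-gene NLR/non-NLR pattern per chromosome
  chrom_names <- names(chromosomes)
  pattern <- stats::setNames(vector("list", length(chrom_names)), chrom_names)
  chrom_of_group <- sample(chrom_names, length(group_sizes), replace = TRUE)
  for (g in seq_along(group_sizes)) {
    ch <- chrom_of_group[g]
    block <- logical(0)
    for (m in seq_len(group_sizes[g])) {
      block <- c(block, TRUE)
      if (m < group_sizes[g]) block <- c(block, rep(FALSE, sample(0:8, 1)))
    }
    sep <- rep(FALSE, min_between + sample(0:6, 1))
    pattern[[ch]] <- c(pattern[[ch]], sep, block)
  }
  used <- sum(lengths(pattern))
  if (n_genes < used + length(chrom_names)) {
    stop("n_genes too small for the requested layout")
  }
  filler <- n_genes - used
  fill_per <- table(sample(chrom_names, filler, replace = TRUE))
  for (ch in chrom_names) {
    extra <- if (ch %in% names(fill_per)) fill_per[[ch]] else 0
    pattern[[ch]] <- c(pattern[[ch]], rep(FALSE, extra))
  }

  gid <- 0L
  loci <- purrr::map_dfr(chrom_names, function(ch) {
    pat <- pattern[[ch]]
    if (!length(pat)) return(tibble::tibble())
    glen <- sample(1000:3000, length(pat), replace = TRUE)
    inter <- sample(500:8000, length(pat), replace = TRUE)
    starts <- cumsum(inter) + cumsum(c(0, glen[-length(glen)]))
    ids <- sprintf("%s_g%05d", ch, seq_along(pat) + gid)
    gid <<- gid + length(pat)
    tibble::tibble(gene_id = ids, chromosome = ch, start = starts,
                   end = starts + glen,
                   strand = sample(c("+", "-"), length(pat), replace = TRUE),
                   is_nlr = pat)
  })
  truth <- list(singletons = spec$singletons, pairs = spec$pairs,
                triplets = spec$triplets,
                cluster_sizes = sort(as.integer(spec$cluster_sizes)),
                n_nlr = n_nlr)
  attr(loci, "truth") <- truth
  loci
}

# Goldman-Yang style codon rate matrix (uniform codon frequencies),
# scaled to one expected substitution per codon site per unit time
gy94_matrix <- function(omega, kappa) {
  key <- paste("gy94", signif(omega, 10), signif(kappa, 10), sep = "_")
  if (!is.null(the[[key]])) return(the[[key]])
  ct <- codon_tables()
  sense <- ct$sense
  n <- length(sense)
  chars <- strsplit(sense, "")
  Q <- matrix(0, n, n, dimnames = list(sense, sense))
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(chars[[i]] != chars[[j]])
    if (length(d) != 1) next
    r <- 1
    if (transitions[[chars[[i]][d]]] == chars[[j]][d]) r <- r * kappa
    if (ct$aa[sense[i]] != ct$aa[sense[j]]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) / n)   # uniform codon frequencies
  eg <- eigen(Q, symmetric = TRUE)
  the[[key]] <- list(Q = Q, U = eg$vectors, lambda = eg$values, sense = sense)
  the[[key]]
}

#' Simulate codon evolution along a tree
#'
#' Goldman-Yang style codon substitution (transition/transversion ratio
#' `kappa`, nonsynonymous scaling `omega`, uniform codon frequencies)
#' along a `phylo` tree; branch lengths are expected substitutions per
#' codon site.
#'
#' @param tree `phylo` with branch lengths.
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param n_codons Number of codon sites.
#' @param seed Seed.
#' @return Tibble (`id`, `aligned`) of gap-free CDS rows, one per tip
#'   (already aligned since no indels are simulated).
#' @export
simulate_codon_evolution <- function(tree, omega, kappa = 2, n_codons = 300,
                                     seed = 1) {
  set.seed(seed)
  mod <- gy94_matrix(omega, kappa)
  nsense <- length(mod$sense)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- matrix(0L, nrow = nn, ncol = n_codons)
  root <- ntip + 1L
  states[root, ] <- sample.int(nsense, n_codons, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    P <- mod$U %*% diag(exp(mod$lambda * t)) %*% t(mod$U)
    P <- pmax(P, 0); P <- P / rowSums(P)
    states[kid, ] <- vapply(states[par, ], function(s) {
      sample.int(nsense, 1L, prob = P[s, ])
    }, integer(1))
  }
  tibble::tibble(
    id = tree$tip.label,
    aligned = vapply(seq_len(ntip), function(i) {
      paste(mod$sense[states[i, ]], collapse = "")
    }, character(1)))
}

#' Simulate family sizes under the birth-death process
#'
#' Exact Gillespie simulation of the equal-rates linear birth-death
#' process along each branch of a dated tree (per-gene gain and loss
#' rate `lambda`; zero is absorbing).
#'
#' @param tree Ultrametric `phylo`.
#' @param lambda Gain/loss rate per gene per time unit.
#' @param n_families Number of independent families.
#' @param root_dist Function drawing `n` root sizes (default
#'   `1 + rpois(n, 4)`).
#' @param seed Seed.
#' @return Profile tibble: `family_id` plus one count column per tip,
#'   root sizes in `attr(, "truth")`.
#' @export
simulate_bdp_families <- function(tree, lambda, n_families,
                                  root_dist = function(n) 1L + stats::rpois(n, 4),
                                  seed = 1) {
  set.seed(seed)
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  roots <- root_dist(n_families)

  evolve_branch <- function(s, t) {
    if (lambda <= 0 || t <= 0) return(s)
    time <- 0
    repeat {
      if (s == 0L) return(0L)
      rate <- 2 * lambda * s
      time <- time + stats::rexp(1, rate)
      if (time > t) return(s)
      s <- s + sample(c(1L, -1L), 1L)
    }
  }

  prof <- matrix(0L, nrow = n_families, ncol = ntip,
                 dimnames = list(NULL, tree$tip.label))
  for (f in seq_len(n_families)) {
    st <- integer(nn)
    st[root] <- roots[f]
    for (e in seq_len(nrow(tree$edge))) {
      st[tree$edge[e, 2]] <- evolve_branch(st[tree$edge[e, 1]],
                                           tree$edge.length[e])
    }
    prof[f, ] <- st[seq_len(ntip)]
  }
  out <- dplyr::bind_cols(
    tibble::tibble(family_id = sprintf("og%04d", seq_len(n_families))),
    tibble::as_tibble(prof))
  attr(out, "truth") <- tibble::tibble(family_id = out$family_id,
                                       root_size = roots)
  out
}

#' Generate a synthetic qPCR Ct table
#'
#' Random target/reference Ct values with replicate noise, for
#' exercising the 2^-dCt computation.
#'
#' @param n_samples,genes Samples and target genes.
#' @param n_replicates Technical replicates (default 2).
#' @param seed Seed.
#' @return Ct tibble in the [relative_expression()] input layout.
#' @export
gen_ct_table <- function(n_samples = 3, genes = c("NLR1", "NLR2"),
                         n_replicates = 2, seed = 1) {
  set.seed(seed)
  tidyr::expand_grid(sample_id = sprintf("s%02d", seq_len(n_samples)),
                     target_gene = genes,
                     replicate = seq_len(n_replicates)) %>%
    dplyr::mutate(
      ct_reference = stats::runif(dplyr::n(), 20, 26),
      ct_target = .data$ct_reference + stats::rnorm(dplyr::n(), 2, 1.5))
}
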