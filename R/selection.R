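# Codon-level selection analysis: SLAC-style counting over a tree with a
# per-site extended binomial test, and composite-likelihood nucleotide
# divergence.

#' Back-translate a protein alignment to a codon alignment
#'
#' Expands each amino-acid column into its codon triple using the source
#' CDS of every row; protein gaps become `---`. Each CDS must translate
#' (standard code; a trailing stop codon is tolerated and trimmed) to its
#' ungapped protein row.
#'
#' @param protein_msa Tibble (`id`, `aligned`).
#' @param cds Tibble (`id`, `residues`) of nucleotide CDS, ids matching.
#' @return Codon alignment: tibble (`id`, `aligned`) of gapped
#'   nucleotide rows, length divisible by 3, gaps in whole-codon units.
#' @export
backtranslate <- function(protein_msa, cds) {
  rows <- purrr::map_chr(seq_len(nrow(protein_msa)), function(i) {
    id <- protein_msa$id[i]
    j <- match(id, cds$id)
    if (is.na(j)) stop("no CDS for row '", id, "'")
    dna <- toupper(cds$residues[j])
    prot <- gsub("-", "", toupper(protein_msa$aligned[i]), fixed = TRUE)
    naa <- nchar(prot)
    if (nchar(dna) == 3 * (naa + 1)) {
      last <- substr(dna, nchar(dna) - 2, nchar(dna))
      if (is_stop_codon(last)) dna <- substr(dna, 1, nchar(dna) - 3)
    }
    if (nchar(dna) != 3 * naa || translate_cds(dna) != prot) {
      stop("CDS does not translate to protein row '", id, "'")
    }
    codons <- split_codons(dna)
    out <- character(nchar(protein_msa$aligned[i]))
    k <- 0L
    cols <- strsplit(toupper(protein_msa$aligned[i]), "")[[1]]
    for (c0 in seq_along(cols)) {
      if (cols[c0] == "-") out[c0] <- "---"
      else { k <- k + 1L; out[c0] <- codons[k] }
    }
    paste(out, collapse = "")
  })
  tibble::tibble(id = protein_msa$id, aligned = rows)
}

#' Drop codon columns below a coverage threshold
#'
#' Coverage of a codon column is its non-gap row fraction. With
#' `min_coverage = 1` this is complete deletion (any gap removes the
#' column); columns with coverage exactly at the threshold are kept.
#'
#' @param aln Codon alignment tibble (`id`, `aligned`).
#' @param min_coverage Number in \[0, 1\].
#' @return Filtered codon alignment.
#' @export
filter_sites <- function(aln, min_coverage) {
  stopifnot(min_coverage >= 0, min_coverage <= 1)
  cod <- do.call(rbind, lapply(aln$aligned, split_codons))
  cov <- colMeans(cod != "---")
  keep <- cov >= min_coverage
  if (!any(keep)) stop("all codon columns dropped")
  tibble::tibble(id = aln$id,
                 aligned = apply(cod[, keep, drop = FALSE], 1, paste, collapse = ""))
}

# Fitch parsimony for one codon site; returns assigned states for all
# nodes (tips + internals, ape numbering), NA for missing tips.
# Ties break toward the parent state; root ties by observed codon
# frequency, then lexicographically.
fitch_site <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) {
    sets[[i]] <- if (is.na(tip_states[i])) NULL else tip_states[i]  # NULL = any
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  # postorder over internal nodes
  ord <- rev(unique(tree$edge[, 1]))  # parents in edge matrix, reversed = post
  for (nd in ord) {
    kid_sets <- Filter(Negate(is.null), sets[children[[as.character(nd)]]])
    if (!length(kid_sets)) { sets[[nd]] <- NULL; next }
    inter <- Reduce(intersect, kid_sets)
    sets[[nd]] <- if (length(inter)) inter else Reduce(union, kid_sets)
  }
  freq <- table(tip_states[!is.na(tip_states)])
  pick <- function(cands, parent_state = NULL) {
    if (!is.null(parent_state) && parent_state %in% cands) return(parent_state)
    f <- freq[cands]; f[is.na(f)] <- 0
    cands <- cands[f == max(f)]
    sort(cands)[1]
  }
  assign <- rep(NA_character_, ntip + nnode)
  rootset <- sets[[root]]
  if (is.null(rootset)) return(assign)  # fully missing site
  assign[root] <- pick(rootset)
  # preorder down
  pre <- unique(tree$edge[, 1])
  for (nd in pre) {
    for (kid in children[[as.character(nd)]]) {
      if (kid <= ntip) { assign[kid] <- tip_states[kid]; next }
      s <- sets[[kid]]
      assign[kid] <- if (is.null(s)) assign[nd] else pick(s, assign[nd])
    }
  }
  assign
}

#' SLAC-style per-site selection analysis
#'
#' Ancestral codons are reconstructed per site by Fitch parsimony (ties
#' toward the parent state; root ties by codon frequency). Substitutions
#' on each branch are decomposed into synonymous and nonsynonymous
#' fractional counts by averaging over all shortest mutational pathways
#' (stop-avoiding, Nei-Gojobori weighting). Expected synonymous and
#' nonsynonymous site counts come from codon-specific synonymous site
#' fractions averaged over the observed codons of the site. Each site
#' gets a two-tailed extended binomial test of its nonsynonymous count
#' against the neutral expectation EN / (EN + ES), with positive /
#' negative calls at `p <= alpha`.
#'
#' @param aln Codon alignment tibble (`id`, `aligned`).
#' @param tree `phylo` whose tip labels match the alignment ids (not
#'   needed for 2 sequences).
#' @param alpha Per-site significance level (default 0.1).
#' @return An `nlr_slac` object: `sites` tibble (site, ES, EN, SS, NS,
#'   dN, dS, p_value, call) and summary fields `n_sequences`, `dN`,
#'   `dS`, `omega`, `psc_count`, `nsc_count`. `tidy()` returns the site
#'   table, `glance()` the summary row.
#' @export
slac <- function(aln, tree = NULL, alpha = 0.1) {
  cod <- do.call(rbind, lapply(aln$aligned, split_codons))
  rownames(cod) <- aln$id
  cod[cod == "---"] <- NA
  if (any(is_stop_codon(stats::na.omit(as.vector(cod))))) {
    stop("internal stop codons in alignment")
  }
  nsites <- ncol(cod)
  nseq <- nrow(cod)
  site_calls <- nseq >= 3
  if (site_calls) {
    stopifnot(!is.null(tree))
    if (!setequal(tree$tip.label, aln$id)) stop("tree tips must match alignment ids")
    tree <- stats::reorder(tree, "cladewise")
    cod <- cod[tree$tip.label, , drop = FALSE]
  }

  ES <- EN <- SS <- NS <- numeric(nsites)
  n_subs <- numeric(nsites)   # codon substitution events (parsimony changes)
  for (s in seq_len(nsites)) {
    obs <- stats::na.omit(cod[, s])
    if (!length(obs)) next
    es <- mean(codon_syn_sites(obs))
    ES[s] <- es; EN[s] <- 3 - es
    if (site_calls) {
      st <- fitch_site(tree, cod[, s])
      for (e in seq_len(nrow(tree$edge))) {
        a <- st[tree$edge[e, 1]]; b <- st[tree$edge[e, 2]]
        if (is.na(a) || is.na(b) || a == b) next
        pc <- codon_path_counts(a, b)
        SS[s] <- SS[s] + pc[["ns"]]
        NS[s] <- NS[s] + pc[["nn"]]
        n_subs[s] <- n_subs[s] + 1
      }
    } else {
      # two sequences: direct pairwise counting
      a <- cod[1, s]; b <- cod[2, s]
      if (!is.na(a) && !is.na(b) && a != b) {
        pc <- codon_path_counts(a, b)
        SS[s] <- SS[s] + pc[["ns"]]
        NS[s] <- NS[s] + pc[["nn"]]
        n_subs[s] <- n_subs[s] + 1
      }
    }
  }

  dN_site <- ifelse(EN > 0, NS / EN, 0)
  dS_site <- ifelse(ES > 0, SS / ES, 0)
  dN <- sum(NS) / sum(EN)
  dS <- sum(SS) / sum(ES)
  omega <- if (dS == 0 && dN == 0) 0 else if (dS == 0) Inf else dN / dS

  # extended binomial tail with fractional counts via regularised beta:
  # P(X >= k) for X ~ Bin(n, p) extended to real k, n
  tail_ge <- function(k, n, p) {
    if (k <= 0) return(1)
    if (k > n) return(0)
    stats::pbeta(p, k, n - k + 1)
  }
  p_value <- rep(NA_real_, nsites)
  call <- rep("neutral", nsites)
  if (site_calls) {
    for (s in seq_len(nsites)) {
      n <- SS[s] + NS[s]
      if (n == 0) { p_value[s] <- 1; next }
      p0 <- EN[s] / (EN[s] + ES[s])
      p_up <- tail_ge(NS[s], n, p0)          # excess nonsynonymous
      p_dn <- 1 - tail_ge(NS[s] + 1e-9, n, p0)
      p_value[s] <- min(1, 2 * min(p_up, p_dn))
      if (p_value[s] <= alpha) {
        if (dN_site[s] > dS_site[s]) call[s] <- "positive"
        else if (dN_site[s] < dS_site[s]) call[s] <- "negative"
      }
    }
  }

  sites <- tibble::tibble(site = seq_len(nsites), ES = ES, EN = EN,
                          SS = SS, NS = NS, n_subs = n_subs,
                          dN = dN_site, dS = dS_site,
                          p_value = p_value, call = call)
  structure(list(sites = sites, n_sequences = nseq, dN = dN, dS = dS,
                 omega = omega,
                 psc_count = sum(call == "positive"),
                 nsc_count = sum(call == "negative"),
                 alpha = alpha),
            class = "nlr_slac")
}

#' @export
print.nlr_slac <- function(x, ...) {
  cat("<nlr_slac> ", x$n_sequences, " sequences, ", nrow(x$sites), " codon sites\n",
      "  dN ", signif(x$dN, 4), "  dS ", signif(x$dS, 4),
      "  omega ", signif(x$omega, 4),
      "  PSC ", x$psc_count, "  NSC ", x$nsc_count, "\n", sep = "")
  invisible(x)
}

#' @rdname slac
#' @param x,object An `nlr_slac` object.
#' @param ... Unused.
#' @export
tidy.nlr_slac <- function(x, ...) x$sites

#' @rdname slac
#' @export
glance.nlr_slac <- function(x, ...) {
  tibble::tibble(n_sequences = x$n_sequences, dN = x$dN, dS = x$dS,
                 omega = x$omega, psc_count = x$psc_count,
                 nsc_count = x$nsc_count, alpha = x$alpha)
}

#' @rdname slac
#' @export
autoplot.nlr_slac <- function(object, ...) {
  df <- object$sites %>%
    dplyr::mutate(dnds = .data$dN - .data$dS)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$site, y = .data$dnds,
                                   colour = .data$call)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "codon site", y = "dN - dS", colour = "call") +
    ggplot2::theme_minimal()
}

#' Composite-likelihood evolutionary divergence
#'
#' Mean number of base substitutions per site over all sequence pairs
#' under the Tamura-Nei (TN93) model, with base frequencies estimated
#' once from the pooled alignment (the composite-likelihood pooling);
#' columns containing gaps or ambiguity are removed first (complete
#' deletion). Saturated pairs (logarithm argument non-positive) are
#' excluded with a warning.
#'
#' @param aln Nucleotide alignment tibble (`id`, `aligned`), at least 2
#'   rows and 50 complete columns.
#' @return `pi`, the mean pairwise distance, with the pairwise distance
#'   matrix in `attr(, "distances")`.
#' @export
mcl_divergence <- function(aln) {
  if (nrow(aln) < 2) stop("need at least 2 sequences")
  m <- do.call(rbind, strsplit(toupper(aln$aligned), ""))
  keep <- apply(m, 2, function(col) all(col %in% DNA4))
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 50) stop("fewer than 50 complete columns after deletion")
  g <- table(factor(as.vector(m), levels = DNA4)) / length(m)
  gA <- g[["A"]]; gC <- g[["C"]]; gG <- g[["G"]]; gT <- g[["T"]]
  gR <- gA + gG; gY <- gC + gT
  n <- nrow(m); L <- ncol(m)
  D <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  dropped <- 0L
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- m[i, ]; b <- m[j, ]
    diff <- a != b
    P1 <- sum(diff & a %in% c("A", "G") & b %in% c("A", "G")) / L
    P2 <- sum(diff & a %in% c("C", "T") & b %in% c("C", "T")) / L
    Q <- sum(diff) / L - P1 - P2
    w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
    w2 <- 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY)
    w3 <- 1 - Q / (2 * gR * gY)
    if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
      dropped <- dropped + 1L
      D[i, j] <- D[j, i] <- NA
      next
    }
    d <- -(2 * gA * gG / gR) * log(w1) - (2 * gC * gT / gY) * log(w2) -
      2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) * log(w3)
    D[i, j] <- D[j, i] <- d
    vals <- c(vals, d)
  }
  if (dropped > 0) warning(dropped, " saturated pair(s) excluded")
  pi_hat <- mean(vals)
  attr(pi_hat, "distances") <- D
  pi_hat
}
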