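# NB-domain phylogeny machinery: coverage filter, progressive alignment,
# pairwise ML distances under JTT, neighbor joining with bootstrap
# support, outgroup rerooting and support-threshold clade collapsing.

#' Filter sequences by domain coverage
#'
#' Retains sequences covering at least `min_fraction` of the reference
#' domain length (sequences strictly below the threshold are excluded,
#' so exactly 50% of the domain is kept at the default).
#'
#' @param seqs Tibble (`id`, `residues`).
#' @param reference_domain_length Full-length reference domain size
#'   (residues), positive.
#' @param min_fraction Minimum length fraction (default 0.5).
#' @return The retained subset of `seqs`.
#' @export
filter_by_domain_coverage <- function(seqs, reference_domain_length,
                                      min_fraction = 0.5) {
  stopifnot(reference_domain_length > 0)
  dplyr::filter(seqs, nchar(.data$residues) / reference_domain_length >= min_fraction)
}

# 3-mer cosine distance between two protein strings
kmer_cosine_dist <- function(a, b, k = 3) {
  km <- function(x) {
    n <- nchar(x)
    if (n < k) return(table(x))
    table(substring(x, 1:(n - k + 1), k:n))
  }
  ta <- km(a); tb <- km(b)
  keys <- union(names(ta), names(tb))
  va <- as.numeric(ta[keys]); va[is.na(va)] <- 0
  vb <- as.numeric(tb[keys]); vb[is.na(vb)] <- 0
  1 - sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

# profile = list(ids, mat) with mat a character matrix (rows x columns)
profile_freqs <- function(mat) {
  F <- matrix(0, nrow = ncol(mat), ncol = 20)
  for (a in seq_along(AA20)) F[, a] <- colMeans(mat == AA20[a])
  F
}

align_profiles <- function(p1, p2, gap_open = 10, gap_ext = 1) {
  F1 <- profile_freqs(p1$mat); F2 <- profile_freqs(p2$mat)
  S <- F1 %*% blosum62() %*% t(F2)
  al <- .affine_align_cpp(S, gap_open, gap_ext, 0L, TRUE)
  path <- al$path
  n1 <- nrow(p1$mat); n2 <- nrow(p2$mat)
  cols1 <- path[, 1]; cols2 <- path[, 2]
  newmat <- matrix("-", nrow = n1 + n2, ncol = nrow(path))
  newmat[seq_len(n1), cols1 > 0] <- p1$mat[, cols1[cols1 > 0], drop = FALSE]
  newmat[n1 + seq_len(n2), cols2 > 0] <- p2$mat[, cols2[cols2 > 0], drop = FALSE]
  list(ids = c(p1$ids, p2$ids), mat = newmat)
}

#' Progressive multiple alignment of protein sequences
#'
#' A deterministic progressive aligner: UPGMA guide tree on 3-mer cosine
#' distances, then profile-profile Needleman-Wunsch with BLOSUM62 column
#' expected scores and affine gaps (open 10, extend 1).
#'
#' @param seqs Tibble (`id`, `residues`), at least 2 rows.
#' @param gap_open,gap_ext Affine gap penalties.
#' @return Aligned block: tibble (`id`, `aligned`) in input row order,
#'   all rows equal length.
#' @export
progressive_align <- function(seqs, gap_open = 10, gap_ext = 1) {
  n <- nrow(seqs)
  if (n < 2) stop("need at least 2 sequences")
  profiles <- lapply(seq_len(n), function(i) {
    list(ids = seqs$id[i],
         mat = matrix(strsplit(toupper(seqs$residues[i]), "")[[1]], nrow = 1))
  })
  if (n == 2) {
    merged <- align_profiles(profiles[[1]], profiles[[2]], gap_open, gap_ext)
  } else {
    D <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kmer_cosine_dist(seqs$residues[i], seqs$residues[j])
    }
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    nodes <- vector("list", n - 1)
    for (m in seq_len(n - 1)) {
      pick <- function(x) if (x < 0) profiles[[-x]] else nodes[[x]]
      nodes[[m]] <- align_profiles(pick(hc$merge[m, 1]), pick(hc$merge[m, 2]),
                                   gap_open, gap_ext)
    }
    merged <- nodes[[n - 1]]
  }
  aligned <- apply(merged$mat, 1, paste, collapse = "")
  tibble::tibble(id = merged$ids, aligned = aligned) %>%
    dplyr::slice(match(seqs$id, merged$ids))
}

# JTT rate matrix (PAML order = AA20) with eigendecomposition, cached.
# Exchangeabilities and stationary frequencies come from phangorn's
# bundled JTT table.
jtt_model <- function() {
  if (!is.null(the$jtt)) return(the$jtt)
  jtt <- get(".JTT", envir = asNamespace("phangorn"))
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- jtt$Q
  S <- S + t(S)
  pi <- as.numeric(jtt$bf); pi <- pi / sum(pi)
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)           # one expected substitution per unit
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  the$jtt <- list(pi = pi, Q = Q,
                  U = diag(1 / d) %*% eg$vectors,
                  Uinv = t(eg$vectors) %*% diag(d),
                  lambda = eg$values)
  the$jtt
}

jtt_pmat <- function(d) {
  m <- jtt_model()
  P <- m$U %*% diag(exp(m$lambda * d)) %*% m$Uinv
  pmax(P, 1e-12)
}

#' Pairwise maximum-likelihood distance under the JTT model
#'
#' Maximises the likelihood of the observed residue pairs over shared
#' non-gap columns: d maximising sum over sites of
#' log(pi_a P_ab(d)), searched on [1e-6, 10].
#'
#' @param a,b Aligned rows (equal-length gapped strings).
#' @return Distance in substitutions per site.
#' @export
jtt_distance <- function(a, b) {
  ca <- match(strsplit(toupper(a), "")[[1]], AA20)
  cb <- match(strsplit(toupper(b), "")[[1]], AA20)
  if (length(ca) != length(cb)) stop("rows must have equal length")
  ok <- !is.na(ca) & !is.na(cb)
  if (!any(ok)) stop("no shared non-gap columns")
  if (sum(ok) < 20) warning("fewer than 20 shared columns; distance unstable")
  N <- matrix(0, 20, 20)
  tab <- table(factor(ca[ok], levels = 1:20), factor(cb[ok], levels = 1:20))
  N <- N + tab
  m <- jtt_model()
  nll <- function(d) {
    P <- jtt_pmat(d)
    -sum(N * log(m$pi * P))
  }
  stats::optimize(nll, interval = c(1e-6, 10), tol = 1e-6)$minimum
}

#' All-pairs JTT distance matrix of an aligned block
#'
#' @param msa Tibble (`id`, `aligned`).
#' @return Symmetric matrix of [jtt_distance()] values with row/col names.
#' @export
jtt_distance_matrix <- function(msa) {
  n <- nrow(msa)
  D <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- jtt_distance(msa$aligned[i], msa$aligned[j])
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) with negative branch
#' lengths clamped to zero.
#'
#' @param D Symmetric distance matrix with zero diagonal and labelled rows.
#' @return An unrooted `phylo` tree.
#' @export
build_nj_tree <- function(D) {
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)) || any(diag(D) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for the NJ tree of an aligned block
#'
#' Resamples alignment columns with replacement, rebuilds the JTT-NJ
#' tree per replicate, and maps bipartition frequencies (percent of
#' replicates containing each internal edge) onto the full-data tree as
#' node labels.
#'
#' @param msa Tibble (`id`, `aligned`).
#' @param n Number of bootstrap replicates (default 100).
#' @param seed Seed for column resampling.
#' @return The full-data NJ `phylo` tree, `node.label` holding integer
#'   supports 0-100.
#' @export
bootstrap_support <- function(msa, n = 100, seed = 1) {
  chmat <- do.call(rbind, strsplit(toupper(msa$aligned), ""))
  rownames(chmat) <- msa$id
  full <- build_nj_tree(jtt_distance_matrix(msa))
  set.seed(seed)
  reps <- vector("list", n)
  for (b in seq_len(n)) {
    cols <- sample.int(ncol(chmat), ncol(chmat), replace = TRUE)
    rmat <- chmat[, cols, drop = FALSE]
    rmsa <- tibble::tibble(id = msa$id,
                           aligned = apply(rmat, 1, paste, collapse = ""))
    reps[[b]] <- build_nj_tree(jtt_distance_matrix(rmsa))
  }
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- n
  full$node.label <- as.character(round_half_up(100 * counts / n))
  full
}

#' Reroot a tree on an outgroup
#'
#' @param tree A `phylo` tree.
#' @param outgroup_id Tip label to place as sister to everything else.
#' @return A rooted `phylo` tree.
#' @export
reroot_tree <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label) {
    stop("outgroup '", outgroup_id, "' not in tree")
  }
  ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
}

#' Collapse weakly supported clades into polytomies
#'
#' Contracts every internal edge whose child node's bootstrap support is
#' below `min_support` into a polytomy (the contracted edge's length is
#' dropped, as in the usual consensus-tree convention). `min_support = 0`
#' is the identity; a threshold above 100 yields a star tree.
#'
#' @param tree A `phylo` with numeric `node.label` supports.
#' @param min_support Keep internal edges with support >= `min_support`.
#' @return A `phylo`, possibly with polytomies.
#' @export
collapse_clades <- function(tree, min_support) {
  if (is.null(tree$node.label)) stop("tree has no support labels")
  ntip <- length(tree$tip.label)
  support <- suppressWarnings(as.numeric(tree$node.label))
  root <- ntip + 1L
  el <- tree$edge.length %||% rep(0, nrow(tree$edge))
  kids <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  elen <- function(node) el[which(tree$edge[, 2] == node)]
  lab <- function(node) {
    l <- tree$tip.label[node]
    gsub("([(),:;])", "_", l)
  }
  build <- function(node, extra) {
    if (node <= ntip) {
      return(paste0(lab(node), ":", format(elen(node) + extra, digits = 12)))
    }
    items <- unlist(lapply(kids(node), build, extra = 0))
    sup <- support[node - ntip]
    len <- if (node == root) 0 else elen(node)
    if (node != root && !is.na(sup) && sup < min_support) {
      # contract: splice children into the parent's polytomy
      return(unlist(lapply(kids(node), build, extra = extra)))
    }
    suplab <- if (is.na(sup)) "" else format(sup)
    paste0("(", paste(items, collapse = ","), ")", suplab, ":",
           format(len + extra, digits = 12))
  }
  items <- unlist(lapply(kids(root), build, extra = 0))
  nwk <- paste0("(", paste(items, collapse = ","), ");")
  out <- ape::read.tree(text = nwk)
  out
}
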