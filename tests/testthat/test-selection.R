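test_that("back-translation expands columns to codons and validates the CDS", {
  msa <- tibble::tibble(id = c("a", "b"), aligned = c("M-K", "MLK"))
  cds <- tibble::tibble(id = c("a", "b"), residues = c("ATGAAA", "ATGCTGAAA"))
  ca <- backtranslate(msa, cds)
  expect_equal(ca$aligned, c("ATG---AAA", "ATGCTGAAA"))

  bad <- tibble::tibble(id = c("a", "b"), residues = c("ATGAAA", "ATGCTGGGG"))
  expect_error(backtranslate(msa, bad), "row 'b'")

  # round trip on simulated protein/CDS pairs (with a trailing stop)
  set.seed(23)
  for (i in 1:20) {
    prot <- rand_protein(sample(10:40, 1))
    cds1 <- nlrforge:::protein_to_cds(prot)
    out <- backtranslate(tibble::tibble(id = "x", aligned = prot),
                         tibble::tibble(id = "x", residues = paste0(cds1, "TAA")))
    expect_equal(nlrforge:::translate_cds(out$aligned), prot)
  }
})

test_that("site filtering drops codon columns below the coverage threshold", {
  rows <- c("AAATTTGGG", "AAA---GGG", "AAATTTGGG", "AAATTT---", "AAATTTGGG")
  aln <- tibble::tibble(id = paste0("s", 1:5), aligned = rows)
  # coverages: 1.0, 0.8, 0.8
  expect_equal(unique(nchar(filter_sites(aln, 0.8)$aligned)), 9)   # kept at 80%
  expect_equal(unique(nchar(filter_sites(aln, 0.81)$aligned)), 3)  # below -> dropped
  expect_equal(unique(nchar(filter_sites(aln, 1)$aligned)), 3)     # complete deletion
  expect_equal(filter_sites(aln, 0), aln)
  expect_error(filter_sites(tibble::tibble(id = "a", aligned = "---"), 0.5),
               "all codon columns dropped")
})

test_that("SLAC counts synonymous and nonsynonymous changes as in hand examples", {
  ident <- tibble::tibble(id = c("a", "b", "c"),
                          aligned = rep("ATGAAACCC", 3))
  tr <- ape::read.tree(text = "(a:1,(b:1,c:1):1);")
  s0 <- slac(ident, tr)
  expect_equal(s0$dN, 0)
  expect_equal(s0$dS, 0)
  expect_equal(s0$omega, 0)
  expect_equal(s0$psc_count + s0$nsc_count, 0)

  # two sequences, Glu GAA vs GAG: one synonymous change
  pair <- slac(tibble::tibble(id = c("a", "b"), aligned = c("GAA", "GAG")))
  expect_equal(pair$sites$SS, 1)
  expect_equal(pair$sites$NS, 0)
  expect_gt(pair$dS, 0)
  expect_equal(pair$dN, 0)

  # Nei-Gojobori pathway averaging: AAA (Lys) vs AGG (Arg), two paths
  # AAA->AGA(Arg)->AGG: nonsyn + syn; AAA->AAG(Lys)->AGG: syn + nonsyn
  pc <- nlrforge:::codon_path_counts("AAA", "AGG")
  expect_equal(unname(pc["ns"]), 1)
  expect_equal(unname(pc["nn"]), 1)
})

test_that("total per-site substitutions equal the parsimony count of codon characters", {
  set.seed(30)
  tr <- ape::rcoal(6)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * 1.5
  aln <- simulate_codon_evolution(tr, omega = 0.5, n_codons = 60, seed = 31)
  res <- slac(aln, tr)
  cod <- do.call(rbind, lapply(aln$aligned, nlrforge:::split_codons))
  rownames(cod) <- aln$id
  # parsimony length per site on codon characters via phangorn
  pd <- phangorn::phyDat(cod[tr$tip.label, , drop = FALSE], type = "USER",
                         levels = sort(unique(as.vector(cod))))
  plen <- phangorn::parsimony(tr, pd, site = "site")   # per unique pattern
  persite <- plen[attr(pd, "index")]
  expect_equal(sum(res$sites$n_subs), sum(persite), tolerance = 1e-9)
  # nucleotide steps are at least one per codon substitution event
  expect_true(all(res$sites$SS + res$sites$NS >= res$sites$n_subs - 1e-9))
})

test_that("omega is invariant to row order and codon-column permutation", {
  tr <- ape::rcoal(5)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length)
  aln <- simulate_codon_evolution(tr, omega = 0.4, n_codons = 50, seed = 32)
  base <- slac(aln, tr)$omega
  perm_rows <- aln[sample(nrow(aln)), ]
  expect_equal(slac(perm_rows, tr)$omega, base)
  cod <- do.call(rbind, lapply(aln$aligned, nlrforge:::split_codons))
  set.seed(1)
  cols <- sample(ncol(cod))
  perm_cols <- tibble::tibble(id = aln$id,
                              aligned = apply(cod[, cols], 1, paste, collapse = ""))
  expect_equal(slac(perm_cols, tr)$omega, base)
})

test_that("composite-likelihood divergence matches closed-form oracles", {
  a <- strrep("ACGT", 30)
  expect_equal(as.numeric(mcl_divergence(
    tibble::tibble(id = c("x", "y"), aligned = c(a, a)))), 0, tolerance = 1e-12)

  # one difference in 100 sites: near p = 0.01, Jukes-Cantor says
  # -(3/4) log(1 - 4p/3) = 0.01005; TN93 must agree within 10%
  a100 <- strrep("ACGT", 25)
  b100 <- sub("^A", "G", a100)
  d <- as.numeric(mcl_divergence(tibble::tibble(id = c("x", "y"),
                                                aligned = c(a100, b100))))
  expect_gt(d, 0.009); expect_lt(d, 0.0115)

  expect_error(mcl_divergence(tibble::tibble(id = "x", aligned = a)),
               "at least 2")
  expect_error(mcl_divergence(tibble::tibble(id = c("x", "y"),
                                             aligned = c("ACGT", "ACGT"))),
               "fewer than 50")
})

test_that("divergence pools pairs on a star phylogeny", {
  set.seed(33)
  star <- ape::read.tree(text = "(a:0.025,b:0.025,c:0.025,d:0.025);")
  est <- vapply(1:10, function(s) {
    aln <- simulate_codon_evolution(star, omega = 1, n_codons = 400, seed = 100 + s)
    # codon branch lengths: ~0.05 substitutions/codon between pairs
    as.numeric(mcl_divergence(aln))
  }, numeric(1))
  # expected pairwise divergence 0.05 per codon site = ~0.0167 per nt site
  expect_equal(mean(est), 0.05 / 3, tolerance = 0.1)
})
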