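test_that("transcriptome generator hits the requested short-transcript fraction", {
  tx <- gen_transcriptome(1000, nlr_fraction = 0.3, short_fraction = 0.7,
                          seed = 13)
  tr <- attr(tx, "truth")
  nlr <- tr[tr$is_nlr, ]
  expect_equal(mean(nlr$is_short), 0.7, tolerance = 0.043)  # within 3 points
  expect_equal(mean(tr$is_nlr), 0.3, tolerance = 0.15)
  # short means what it says
  lens <- nchar(tx$residues[match(nlr$id[nlr$is_short], tx$id)])
  expect_true(all(lens < 700))
})

test_that("planted genome layouts are recovered exactly by the cluster caller", {
  for (seed in 1:5) {
    spec <- list(singletons = 3, pairs = 2, triplets = 2, cluster_sizes = c(4, 7))
    lay <- gen_genome_layout(c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6), 500,
                             spec, seed = seed)
    truth <- attr(lay, "truth")
    s <- summarize_clusters(call_clusters(lay), truth$n_nlr)
    expect_equal(s$singletons, truth$singletons)
    expect_equal(s$pairs, truth$pairs)
    expect_equal(s$triplets, truth$triplets)
    expect_equal(s$clusters, length(truth$cluster_sizes))
    expect_equal(s$grouped,
                 2 * truth$pairs + 3 * truth$triplets + sum(truth$cluster_sizes))
  }
})

test_that("a proportional random layout gives calibrated chi-square p-values", {
  set.seed(17)
  lens <- c(c1 = 3e6, c2 = 2e6, c3 = 1e6)
  p <- replicate(1000, {
    counts <- as.vector(stats::rmultinom(1, 60, lens / sum(lens)))
    chromosome_chisq(counts, lens)$p_value
  })
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("codon simulation responds to omega and degenerates sensibly", {
  tr <- balanced_tree5()
  tr$edge.length <- tr$edge.length / 10
  ratio <- vapply(c(0.1, 1, 5), function(om) {
    aln <- simulate_codon_evolution(tr, omega = om, n_codons = 200, seed = 21)
    res <- slac(aln, tr)
    sum(res$sites$NS) / max(sum(res$sites$SS), 1)
  }, numeric(1))
  expect_false(is.unsorted(ratio))  # realized NS/SS grows with omega

  zero <- tr; zero$edge.length[] <- 0
  aln0 <- simulate_codon_evolution(zero, omega = 1, n_codons = 30, seed = 22)
  expect_equal(length(unique(aln0$aligned)), 1)  # identical leaves
})

test_that("reference NB sets plant recoverable motifs that shuffling destroys", {
  ref <- gen_reference_nb_set(n = 40, length = 120, seed = 31)
  truth <- attr(ref, "truth")
  planted <- unique(truth$motif)
  m <- elicit_motifs(ref, n_motifs = 1, width = 12, seed = 1)
  # EM may settle one register off; demand >= 10 of 12 aligned matches
  overlap <- function(a, b) {
    best <- 0
    for (sh in -2:2) {
      ia <- max(1, 1 + sh):min(nchar(a), nchar(b) + sh)
      ib <- ia - sh
      hits <- sum(strsplit(a, "")[[1]][ia] == strsplit(b, "")[[1]][ib])
      best <- max(best, hits)
    }
    best
  }
  expect_gte(max(vapply(planted, overlap, numeric(1), b = m[[1]]$consensus)), 10)

  set.seed(32)
  shuf <- ref
  shuf$residues <- vapply(ref$residues, function(s)
    paste(sample(strsplit(s, "")[[1]]), collapse = ""), character(1))
  m2 <- elicit_motifs(shuf, n_motifs = 1, width = 12, seed = 1)
  expect_lt(max(vapply(planted, overlap, numeric(1), b = m2[[1]]$consensus)), 10)
})
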