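test_that("coverage filtering excludes sequences strictly below the threshold", {
  seqs <- tibble::tibble(id = c("a", "b", "c"),
                         residues = c(rand_protein(49), rand_protein(50),
                                      rand_protein(100)))
  kept <- filter_by_domain_coverage(seqs, 100, 0.5)
  expect_setequal(kept$id, c("b", "c"))
  expect_equal(filter_by_domain_coverage(seqs, 100, 0), seqs)
})

test_that("pairwise alignment is optimal against the exhaustive DP oracle", {
  al <- progressive_align(tibble::tibble(id = c("a", "b"),
                                         residues = c("MKLV", "MKV")))
  expect_equal(align_score(al), oracle_nw("MKLV", "MKV"))
  expect_equal(gsub("-", "", al$aligned[2]), "MKV")

  set.seed(13)
  for (i in 1:25) {
    a <- rand_protein(sample(5:12, 1)); b <- rand_protein(sample(5:12, 1))
    al <- progressive_align(tibble::tibble(id = c("a", "b"),
                                           residues = c(a, b)))
    expect_equal(align_score(al), oracle_nw(a, b), label = paste(a, b))
  }

  ident <- progressive_align(tibble::tibble(id = c("a", "b"),
                                            residues = c("MKWQN", "MKWQN")))
  expect_equal(ident$aligned, c("MKWQN", "MKWQN"))   # gapless self-alignment
  expect_error(progressive_align(tibble::tibble(id = "a", residues = "MK")),
               "at least 2")
})

test_that("multiple alignment keeps all rows, equal widths, width at least the longest input", {
  set.seed(14)
  base <- rand_protein(40)
  seqs <- tibble::tibble(id = paste0("s", 1:6),
                         residues = c(base,
                                      vapply(1:5, function(i)
                                        mutate_seq(base, sample(3:12, 1)),
                                        character(1))))
  # give some rows indels
  seqs$residues[3] <- paste0(substr(seqs$residues[3], 1, 18),
                             substr(seqs$residues[3], 25, 40))
  msa <- progressive_align(seqs)
  expect_equal(msa$id, seqs$id)
  widths <- nchar(msa$aligned)
  expect_equal(length(unique(widths)), 1)
  expect_gte(widths[1], max(nchar(seqs$residues)))
  expect_equal(gsub("-", "", msa$aligned), seqs$residues)
})

test_that("JTT distances vanish on identical rows and increase with divergence", {
  row <- strrep("ARNDCQEGHILKMFPSTWYV", 4)
  expect_lt(jtt_distance(row, row), 1e-4)
  expect_error(jtt_distance("----", "AAAA"), "no shared")

  set.seed(15)
  base <- rand_protein(200)
  dists <- vapply(c(5, 20, 60, 120), function(k) {
    jtt_distance(base, mutate_seq(base, k))
  }, numeric(1))
  expect_false(is.unsorted(dists))
})

test_that("neighbor joining reconstructs additive path lengths and rejects bad input", {
  D <- matrix(c(0, 3, 8, 9,
                3, 0, 9, 10,
                8, 9, 0, 5,
                9, 10, 5, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- build_nj_tree(D)
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]], D,
               tolerance = 1e-9)
  expect_error(build_nj_tree(matrix(1, 2, 2)), "symmetric")
})

test_that("bootstrap supports are percentages mapped onto the full-data tree", {
  set.seed(16)
  base <- rand_protein(80)
  far <- mutate_seq(base, 60)
  seqs <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2", "out"),
    residues = c(mutate_seq(base, 2), mutate_seq(base, 2),
                 mutate_seq(far, 2), mutate_seq(far, 2),
                 rand_protein(80)))
  msa <- progressive_align(seqs)
  tr <- bootstrap_support(msa, n = 30, seed = 2)
  sup <- as.numeric(tr$node.label)
  expect_true(all(sup >= 0 & sup <= 100))
  # the (b1,b2) split is unambiguous and must be fully supported
  pair_node <- ape::getMRCA(tr, c("b1", "b2"))
  expect_equal(sup[pair_node - length(tr$tip.label)], 100)
  # determinism for a fixed seed
  tr2 <- bootstrap_support(msa, n = 30, seed = 2)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))
})

test_that("rerooting keeps leaf-to-leaf path lengths; collapsing respects thresholds", {
  set.seed(17)
  base <- rand_protein(60)
  seqs <- tibble::tibble(id = c("a", "b", "c", "d", "Apaf1"),
                         residues = c(mutate_seq(base, 3), mutate_seq(base, 4),
                                      mutate_seq(base, 20), mutate_seq(base, 22),
                                      rand_protein(60)))
  msa <- progressive_align(seqs)
  tr <- bootstrap_support(msa, n = 20, seed = 3)
  ro <- reroot_tree(tr, "Apaf1")
  expect_true(ape::is.rooted(ro))
  ids <- seqs$id
  expect_equal(ape::cophenetic.phylo(ro)[ids, ids],
               ape::cophenetic.phylo(tr)[ids, ids], tolerance = 1e-9)
  expect_error(reroot_tree(tr, "nope"), "not in tree")

  keep <- collapse_clades(tr, 0)
  expect_equal(keep$Nnode, tr$Nnode)             # identity at threshold 0
  star <- collapse_clades(tr, 101)
  expect_equal(star$Nnode, 1)                    # fully collapsed
  # intermediate thresholds keep fully supported splits
  half <- collapse_clades(tr, 50)
  sup <- as.numeric(tr$node.label)
  expect_lte(half$Nnode, tr$Nnode)
  expect_gte(half$Nnode, sum(sup >= 50, na.rm = TRUE))
})
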