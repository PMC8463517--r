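test_that("EM recovers a planted motif and saturates on identical input", {
  ref <- gen_reference_nb_set(n = 50, length = 120,
                              motif_spec = "MKWVQRLNDAGE", seed = 7)
  m <- elicit_motifs(ref, n_motifs = 1, width = 12, seed = 3)
  expect_equal(m[[1]]$consensus, "MKWVQRLNDAGE")

  ident <- tibble::tibble(id = paste0("s", 1:10),
                          residues = rep(strrep("ACDEFGHIKLMNPQRS", 2), 10))
  m2 <- elicit_motifs(ident, n_motifs = 1, width = 8, seed = 1)
  expect_true(all(apply(m2[[1]]$prob, 1, max) >= 0.99))

  expect_error(elicit_motifs(ident[1:3, ], n_motifs = 1, width = 8),
               "at least 5")
  expect_error(elicit_motifs(ident, n_motifs = 5, width = 8),
               "exceeds the shortest")
})

test_that("masking makes the second elicited motif find the second planted signal", {
  set.seed(19)
  a <- "WWHHCCYYWWHH"   # deliberately un-protein-like, unambiguous
  b <- "EEDDKKRREEDD"
  seqs <- vapply(1:40, function(i) {
    left <- rand_protein(20); mid <- rand_protein(15); right <- rand_protein(20)
    paste0(left, a, mid, b, right)
  }, character(1))
  ref <- tibble::tibble(id = paste0("s", 1:40), residues = seqs)
  m <- elicit_motifs(ref, n_motifs = 2, width = 12, seed = 2)
  expect_setequal(vapply(m, `[[`, character(1), "consensus"), c(a, b))
  expect_false(m[[1]]$consensus == m[[2]]$consensus)
})

test_that("motif scan finds the planted positive, reports coordinates, and rejects empty input", {
  ref <- gen_reference_nb_set(n = 30, seed = 1)
  mots <- elicit_motifs(ref, n_motifs = 3, width = 12, seed = 1)
  set.seed(5)
  pos <- ref$residues[1]
  decoys <- vapply(1:100, function(i)
    paste(sample(strsplit(pos, "")[[1]]), collapse = ""), character(1))
  db <- tibble::tibble(id = c("pos", paste0("d", 1:100)),
                       residues = c(pos, decoys))
  hits <- scan_motifs(db, mots, evalue_threshold = 1e-4)
  expect_equal(hits$seq_id, "pos")

  # a planted consensus at 0-based position 10 is located there
  set.seed(8)
  planted <- paste0(rand_protein(10), mots[[1]]$consensus, rand_protein(40))
  h1 <- scan_motifs(tibble::tibble(id = "p", residues = planted), mots[1],
                    evalue_threshold = Inf)
  expect_equal(motif_hits(h1)$start, 10)

  expect_error(scan_motifs(db, list()), "no motifs")
})

test_that("scan p-values are super-uniform on random background sequences", {
  ref <- gen_reference_nb_set(n = 30, seed = 3)
  mots <- elicit_motifs(ref, n_motifs = 2, width = 12, seed = 4)
  set.seed(31)
  rnd <- tibble::tibble(id = paste0("r", 1:400),
                        residues = replicate(400, rand_protein(150)))
  h <- scan_motifs(rnd, mots, evalue_threshold = Inf)
  # super-uniform: P(p <= x) <= x; one-sided KS must not reject
  ks <- suppressWarnings(
    stats::ks.test(h$p_comb, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("decoys scale e-values linearly without removing true hits", {
  ref <- gen_reference_nb_set(n = 20, seed = 6)
  mots <- elicit_motifs(ref, n_motifs = 2, width = 12, seed = 6)
  set.seed(7)
  small <- tibble::tibble(id = c("pos", paste0("d", 1:49)),
                          residues = c(ref$residues[1],
                                       replicate(49, rand_protein(120))))
  big <- dplyr::bind_rows(small,
    tibble::tibble(id = paste0("e", 1:50),
                   residues = replicate(50, rand_protein(120))))
  h1 <- scan_motifs(small, mots, evalue_threshold = Inf)
  h2 <- scan_motifs(big, mots, evalue_threshold = Inf)
  p1 <- h1[h1$seq_id == "pos", ]
  p2 <- h2[h2$seq_id == "pos", ]
  expect_equal(p1$p_comb, p2$p_comb)            # p unchanged by decoys
  expect_equal(p2$e_value / p1$e_value, 2)      # e-value scales with db size
  expect_true("pos" %in% h2$seq_id)
})
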