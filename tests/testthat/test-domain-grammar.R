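test_that("architecture classification is total and consistent over all kind subsets", {
  kinds <- c("CC", "TIR", "RPW8", "NB", "LRR")
  for (mask in 0:31) {
    subset <- kinds[bitwAnd(mask, 2^(0:4)) > 0]
    cls <- classify_architecture(subset)
    expect_equal(nrow(cls), 1)
    expect_equal(cls$is_full_length, all(c("NB", "LRR") %in% subset))
    expect_true(nchar(cls$class_label) > 0)
  }
  # published taxonomy rows
  expect_equal(classify_architecture(c("CC", "NB", "LRR"))$class_label, "CNL")
  expect_equal(classify_architecture(c("TIR", "NB", "LRR"))$class_label, "TNL")
  expect_equal(classify_architecture(c("RPW8", "NB", "LRR"))$class_label, "RNL")
  expect_equal(classify_architecture(c("NB", "LRR"))$class_label, "NL")
  expect_equal(classify_architecture(c("TIR", "NB"))$class_label, "TIR-NB")
  expect_equal(classify_architecture(c("CC", "LRR"))$class_label, "CC-LRR")
  expect_equal(classify_architecture("RPW8")$class_label, "RPW8")
  expect_equal(classify_architecture(character(0))$class_label, "unclassified")
  # the N-terminal-most recognised domain decides the full-length subclass
  pos <- tibble::tibble(kind = c("CC", "TIR", "NB", "LRR"),
                        start = c(50, 5, 120, 300), end = c(80, 40, 260, 400))
  expect_equal(classify_architecture(pos)$class_label, "TNL")
})

test_that("sequence-level detectors call planted CC, TM and nothing on poly-G", {
  # 4 tandem perfect heptads (L at a and d) in a polar context
  heptads <- strrep("LQELADK", 4)
  prot <- paste0(strrep("STNQ", 10), heptads, strrep("QDES", 10))
  d <- detect_domains(prot)
  cc <- d[d$kind == "CC", ]
  expect_equal(nrow(cc), 1)
  expect_lte(cc$start, nchar(prot) - 40 - 28)  # covers the repeat region
  expect_gte(cc$end, 40 + 20)

  # 19-residue poly-isoleucine: KD hydropathy 4.5 > 1.8
  tmprot <- paste0(strrep("STNQ", 8), strrep("I", 19), strrep("QDES", 8))
  dtm <- detect_domains(tmprot)
  expect_true("TM" %in% dtm$kind)
  tm <- dtm[dtm$kind == "TM", ]
  expect_equal(max(dtm$score[dtm$kind == "TM"]), 4.5)

  expect_equal(nrow(detect_domains(strrep("G", 200))), 0)
})

test_that("planted LRR repeats are called and annotations come back sorted", {
  cons <- synthetic_domain_consensus()
  prot <- paste0(strrep("TSNQ", 8), cons$LRR, strrep("DQES", 8))
  d <- detect_domains(prot)
  expect_true("LRR" %in% d$kind)
  expect_false(is.unsorted(d$start))
  lrr <- d[d$kind == "LRR", ]
  expect_lte(abs(lrr$start[1] - 32), 8)
})

test_that("end-to-end detect and classify recovers planted architectures", {
  profs <- synthetic_domain_profiles(seed = 1)
  nterm <- profs$nterm[c("TIR", "RPW8")]
  tx <- gen_transcriptome(40, nlr_fraction = 1, short_fraction = 0.5, seed = 11)
  tr <- attr(tx, "truth")
  pred <- vapply(seq_len(nrow(tr)), function(i) {
    d <- detect_domains(tr$protein[i], profs$nb, nterm)
    classify_architecture(d)$class_label
  }, character(1))
  expect_gte(mean(pred == tr$class_label), 0.95)
})

test_that("repertoire summaries tabulate totals, percentages and ignore record order", {
  rec <- tibble::tibble(
    gene_id = paste0("g", 1:10), source = "transcriptome",
    class_label = c(rep("CNL", 3), rep("TNL", 1), rep("TIR", 4), rep("LRR", 2)),
    is_full_length = c(rep(TRUE, 4), rep(FALSE, 6)),
    has_id = FALSE, has_tm = FALSE, n_domains = 2)
  s <- summarize_repertoire(rec)
  g <- glance(s)
  expect_equal(g$total, 10)
  expect_equal(g$total_full, 4)
  expect_equal(g$total_partial, 6)
  expect_equal(g$percent_full, 40)
  expect_equal(sum(tidy(s)$n), g$total)

  s2 <- summarize_repertoire(rec[sample(10), ])
  expect_equal(glance(s2), g)

  single <- summarize_repertoire(rec[1, ])
  expect_equal(glance(single)$total, 1)
  expect_true(glance(single)$percent_full %in% c(0, 100))

  empty <- summarize_repertoire(rec[0, ])
  expect_equal(glance(empty)$total, 0)

  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})
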