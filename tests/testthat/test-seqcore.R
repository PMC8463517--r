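test_that("FASTA records parse with case folding, multi-line bodies and id handling", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ac", "gt", ">b some description", "MKLV"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("a", "b"))
  expect_equal(recs$residues, c("ACGT", "MKLV"))
  expect_equal(recs$alphabet, c("dna", "protein"))

  writeLines(c(">x", "ACGT", ">x", "TTTT", ">bad", "AC1T"), f)
  expect_warning(expect_warning(recs2 <- read_fasta(f), "duplicate"), "non-IUPAC"
  )
  expect_equal(nrow(recs2), 2)
  expect_false(anyDuplicated(recs2$id) > 0)
})

test_that("FASTA write/read round-trips random records", {
  set.seed(11)
  recs <- tibble::tibble(
    id = paste0("s", 1:100),
    alphabet = rep(c("dna", "protein"), each = 50),
    residues = c(replicate(50, rand_dna(sample(5:200, 1))),
                 # "EF" prefix keeps short proteins out of the nucleotide
                 # IUPAC alphabet so inference is unambiguous
                 replicate(50, paste0("EF", rand_protein(sample(5:200, 1))))))
  recs <- recs[order(recs$id), ]
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(back$id, recs$id)
  expect_equal(back$residues, recs$residues)
  expect_equal(back$alphabet, recs$alphabet)
})

test_that("six-frame translation matches known frames and handles short input", {
  fr <- six_frame_translate(tibble::tibble(id = "t", residues = "ATGAAA"))
  expect_equal(nrow(fr), 6)
  expect_equal(fr$peptide[fr$frame == 1], "MK")
  rc <- six_frame_translate(tibble::tibble(id = "t", residues = "TTTCAT"))
  expect_equal(rc$peptide[rc$frame == -1], "MK")
  expect_warning(short <- six_frame_translate(tibble::tibble(id = "s", residues = "AT")),
                 "shorter")
  expect_equal(short$peptide, rep("", 6))
})

test_that("six-frame translation agrees with a codon-table oracle on random sequences", {
  code <- as.list(Biostrings::GENETIC_CODE)
  oracle <- function(s) {
    n <- nchar(s)
    vapply(seq(1, n - 2, by = 3), function(i) {
      cod <- substr(s, i, i + 2)
      aa <- code[[cod]]
      if (is.null(aa)) "X" else aa
    }, character(1)) |> paste(collapse = "")
  }
  set.seed(21)
  for (rep in 1:100) {
    s <- rand_dna(300)
    fr <- six_frame_translate(tibble::tibble(id = "t", residues = s))
    rc <- revcomp(s)
    for (k in 1:3) {
      fwd <- substr(s, k, k + 3 * ((300 - k + 1) %/% 3) - 1)
      rev <- substr(rc, k, k + 3 * ((300 - k + 1) %/% 3) - 1)
      expect_equal(fr$peptide[fr$frame == k], oracle(fwd))
      expect_equal(fr$peptide[fr$frame == -k], oracle(rev))
    }
  }
})

test_that("six-frame translation of the reverse complement swaps frame signs", {
  set.seed(5)
  s <- rand_dna(90)
  a <- six_frame_translate(tibble::tibble(id = "t", residues = s))
  b <- six_frame_translate(tibble::tibble(id = "t", residues = revcomp(s)))
  expect_setequal(a$peptide, b$peptide)
  expect_equal(sort(a$peptide[a$frame > 0]), sort(b$peptide[b$frame < 0]))
})

test_that("frame +1 translation distributes over codon concatenation", {
  set.seed(6)
  tr1 <- function(x) six_frame_translate(tibble::tibble(id = "t", residues = x))$peptide[1]
  a <- rand_dna(30); b <- rand_dna(45)
  expect_equal(tr1(paste0(a, b)), paste0(tr1(a), tr1(b)))
})

test_that("GFF3 I/O converts coordinates, sorts, rejects bad lines and round-trips", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t500\t900\t.\t-\t.\tID=g2",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t300\t250\t.\t+\t.\tID=bad"), f)
  expect_warning(loci <- read_gff3(f), "end < start")
  expect_equal(loci$gene_id, c("g1", "g2"))     # sorted by start
  expect_equal(loci$start[1], 99)               # 1-based inclusive -> 0-based
  expect_equal(loci$end[1], 200)

  out <- withr::local_tempfile(fileext = ".gff3")
  loci$is_nlr <- c(TRUE, FALSE)
  write_gff3(loci, out)
  back <- read_gff3(out)
  expect_equal(back[, c("gene_id", "chromosome", "start", "end", "strand", "is_nlr")],
               loci[, c("gene_id", "chromosome", "start", "end", "strand", "is_nlr")])
})
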