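#' Read a FASTA file into a sequence tibble
#'
#' Sequences are the universal currency of the pipeline and are carried as
#' rows of a tibble with columns `id`, `alphabet` (`"dna"` or `"protein"`)
#' and `residues` (uppercase IUPAC string). Parsing is delegated to
#' [Biostrings::readBStringSet()]; this wrapper uppercases residues,
#' infers the alphabet per record, de-duplicates ids (warning, numeric
#' suffix) and drops records containing non-IUPAC characters (warning).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `alphabet`, `residues`, one row per
#'   record, input order preserved.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "MKLV"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids; suffixing duplicates")
    ids <- make.unique(ids, sep = "_")
  }
  res <- toupper(as.character(ss))
  alphabet <- vapply(res, infer_alphabet, character(1), USE.NAMES = FALSE)
  ok <- !is.na(alphabet)
  if (any(!ok)) {
    warning("dropping ", sum(!ok), " record(s) with non-IUPAC characters: ",
            paste(ids[!ok], collapse = ", "))
  }
  tibble::tibble(id = ids[ok], alphabet = alphabet[ok], residues = unname(res[ok]))
}

# dna if every residue is a nucleotide IUPAC code, protein if amino-acid
# IUPAC; NA if neither alphabet fits
infer_alphabet <- function(x) {
  if (nchar(x) == 0L) return(NA_character_)
  if (grepl("^[ACGTUNRYSWKMBDHV-]+$", x)) return("dna")
  if (grepl("^[ARNDCQEGHILKMFPSTWYVXBZJUO*-]+$", x)) return("protein")
  NA_character_
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id` and `residues`.
#' @param path Output path. Lines wrap at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "residues") %in% names(seqs)))
  ss <- Biostrings::BStringSet(seqs$residues)
  names(ss) <- seqs$id
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Reverse-complement nucleotide sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate transcripts in all six reading frames
#'
#' Whole transcripts (not ORFs) are translated in the three forward and
#' three reverse frames under the standard genetic code; stop codons are
#' kept as `*` and ambiguous codons render as `X`, so downstream motif and
#' profile scans see the complete peptide space of a fragmented
#' transcriptome.
#'
#' @param seqs Tibble of DNA records (columns `id`, `residues`; an
#'   `alphabet` column, if present, must be `"dna"`).
#' @return Tibble with columns `source_id`, `frame` (+1,+2,+3,-1,-2,-3),
#'   `offset_nt` (0-based forward-strand offset of the frame's first
#'   codon) and `peptide`.
#' @export
#' @examples
#' six_frame_translate(tibble::tibble(id = "t1", residues = "ATGAAA"))
six_frame_translate <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(id = names(seqs) %||% paste0("seq", seq_along(seqs)),
                           residues = unname(seqs))
  }
  if ("alphabet" %in% names(seqs) && any(seqs$alphabet != "dna")) {
    stop("six_frame_translate() requires DNA records")
  }
  purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    translate_six_frames_one(seqs$id[i], seqs$residues[i])
  })
}

translate_six_frames_one <- function(id, s) {
  L <- nchar(s)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  if (L < 3L) {
    warning("sequence '", id, "' shorter than one codon; empty translations")
    return(tibble::tibble(source_id = id, frame = frames,
                          offset_nt = c(0L, 1L, 2L, pmax(L - 3L, 0L), pmax(L - 4L, 0L), pmax(L - 5L, 0L)),
                          peptide = ""))
  }
  rc <- revcomp(s)
  purrr::map_dfr(frames, function(f) {
    k <- abs(f)
    src <- if (f > 0) s else rc
    ncod <- (L - (k - 1L)) %/% 3L
    pep <- if (ncod == 0L) "" else {
      sub <- substr(src, k, k + 3L * ncod - 1L)
      as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                         if.fuzzy.codon = "X",
                                         no.init.codon = TRUE))
    }
    offset <- if (f > 0) k - 1L else L - k - 2L
    tibble::tibble(source_id = id, frame = f, offset_nt = as.integer(offset),
                   peptide = pep)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read gene loci from a GFF3 file
#'
#' Imports gene features via [rtracklayer::import()] and converts the
#' 1-based inclusive GFF coordinates to the package's 0-based half-open
#' convention. Lines with `end < start` are rejected with a warning. An
#' `is_nlr` attribute (`1`/`true`/`yes`), if present, is carried through;
#' otherwise `is_nlr` is `FALSE` and is typically set later from a
#' detection hit list.
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature types to keep (default `"gene"`; `NULL`
#'   keeps everything).
#' @return Tibble of loci sorted by (chromosome, start): `gene_id`,
#'   `chromosome`, `start`, `end` (0-based half-open), `strand`, `is_nlr`.
#' @export
read_gff3 <- function(path, feature_type = "gene") {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- vapply(fields, function(f) {
    length(f) >= 5 && suppressWarnings(as.numeric(f[5]) < as.numeric(f[4]))
  }, logical(1))
  if (any(bad)) {
    warning("rejecting ", sum(bad), " GFF3 line(s) with end < start")
    tmp <- tempfile(fileext = ".gff3")
    keep <- rep(TRUE, length(lines))
    keep[which(body)[bad]] <- FALSE
    writeLines(lines[keep], tmp)
    path <- tmp
  }
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  if (!is.null(feature_type) && "type" %in% names(md)) {
    gr <- gr[as.character(md$type) %in% feature_type]
    md <- S4Vectors::mcols(gr)
  }
  if (length(gr) == 0L) stop("no gene features in ", path)
  ids <- if ("ID" %in% names(md) && !all(is.na(md$ID))) as.character(md$ID)
         else if ("Name" %in% names(md)) as.character(md$Name)
         else paste0("gene", seq_along(gr))
  is_nlr <- rep(FALSE, length(gr))
  if ("is_nlr" %in% names(md)) {
    is_nlr <- tolower(as.character(md$is_nlr)) %in% c("1", "true", "yes")
  }
  out <- tibble::tibble(
    gene_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    is_nlr = is_nlr
  )
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  dplyr::arrange(out, .data$chromosome, .data$start)
}

#' Write gene loci to GFF3
#'
#' Inverse of [read_gff3()]: converts the internal 0-based half-open
#' coordinates back to 1-based inclusive and writes `gene` features with
#' `ID` and `is_nlr` attributes.
#'
#' @param loci Tibble as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end") %in% names(loci)))
  strand <- if ("strand" %in% names(loci)) loci$strand else "+"
  is_nlr <- if ("is_nlr" %in% names(loci)) loci$is_nlr else FALSE
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chromosome,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = strand
  )
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- loci$gene_id
  S4Vectors::mcols(gr)$is_nlr <- ifelse(is_nlr, "1", "0")
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
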