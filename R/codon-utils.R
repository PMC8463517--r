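# Codon tables shared by the selection analysis and the codon-evolution
# simulator. Standard genetic code throughout (from Biostrings).

codon_tables <- function() {
  if (!is.null(the$codon)) return(the$codon)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  stops <- codons[aa == "*"]
  sense <- codons[aa != "*"]
  the$codon <- list(codons = codons, aa = stats::setNames(aa, codons),
                    stops = stops, sense = sense)
  the$codon
}

codon_aa <- function(x) codon_tables()$aa[x]

is_stop_codon <- function(x) x %in% codon_tables()$stops

# expected synonymous sites of a codon: each position contributes the
# fraction of its non-stop single-nucleotide changes that are synonymous
codon_syn_sites <- function(codon) {
  ct <- codon_tables()
  if (is.null(the$syn_sites)) {
    ss <- vapply(ct$sense, function(c0) {
      chars <- strsplit(c0, "")[[1]]
      total <- 0
      for (i in 1:3) {
        alts <- setdiff(DNA4, chars[i])
        muts <- vapply(alts, function(a) {
          x <- chars; x[i] <- a; paste(x, collapse = "")
        }, character(1))
        valid <- muts[!is_stop_codon(muts)]
        if (length(valid)) {
          total <- total + mean(codon_aa(valid) == codon_aa(c0))
        }
      }
      total
    }, numeric(1))
    the$syn_sites <- ss
  }
  the$syn_sites[codon]
}

# average synonymous / nonsynonymous substitution counts between two
# codons over all shortest mutational pathways, excluding pathways that
# pass through a stop codon (falling back to all pathways if every one
# does). Memoised.
codon_path_counts <- function(a, b) {
  key <- paste0(a, b)
  if (is.null(the$path_counts)) the$path_counts <- new.env(parent = emptyenv())
  hit <- the$path_counts[[key]]
  if (!is.null(hit)) return(hit)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  diffpos <- which(ca != cb)
  k <- length(diffpos)
  res <- if (k == 0L) c(ns = 0, nn = 0) else {
    perms <- if (k == 1L) list(diffpos) else {
      pp <- list()
      for (p in combinat_perms(diffpos)) pp[[length(pp) + 1L]] <- p
      pp
    }
    count_one <- function(order) {
      cur <- ca; s <- 0; n <- 0; through_stop <- FALSE
      for (pos in order) {
        nxt <- cur; nxt[pos] <- cb[pos]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        if (is_stop_codon(c2) && c2 != b) through_stop <- TRUE
        if (codon_aa(c1) == codon_aa(c2) &&
            !is_stop_codon(c1) && !is_stop_codon(c2)) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s = s, n = n, stop = as.numeric(through_stop))
    }
    allp <- vapply(perms, count_one, numeric(3))
    ok <- allp["stop", ] == 0
    use <- if (any(ok)) allp[, ok, drop = FALSE] else allp
    c(ns = mean(use["s", ]), nn = mean(use["n", ]))
  }
  the$path_counts[[key]] <- res
  res
}

# all permutations of a small vector (k <= 3 here)
combinat_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in combinat_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# split a gapped nucleotide row into codon strings (length divisible by 3)
split_codons <- function(row) {
  n <- nchar(row)
  if (n %% 3 != 0) stop("alignment length not divisible by 3")
  substring(row, seq(1, n, 3), seq(3, n, 3))
}

translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}
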