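# shared fixture builders; everything is generated in code under fixed seeds

rand_protein <- function(n, alphabet = nlrforge:::AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

mutate_seq <- function(s, k, alphabet = nlrforge:::AA20) {
  ch <- strsplit(s, "")[[1]]
  i <- sample(length(ch), k)
  ch[i] <- sample(alphabet, k, replace = TRUE)
  paste(ch, collapse = "")
}

balanced_tree5 <- function() {
  ape::read.tree(text = "((a:5,b:5):5,(c:7,(d:4,e:4):3):3);")
}

# brute-force O(n^2) transitive-closure cluster oracle: NLR loci i, j are
# linked when <= max_gap non-NLR genes lie between them on the same
# chromosome; clusters are connected components
oracle_clusters <- function(loci, max_gap = 8) {
  loci <- loci[order(loci$chromosome, loci$start), ]
  out <- list()
  for (ch in unique(loci$chromosome)) {
    df <- loci[loci$chromosome == ch, ]
    idx <- which(df$is_nlr)
    if (!length(idx)) next
    n <- length(idx)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      gap <- abs(idx[i] - idx[j]) - 1L
      adj[i, j] <- gap <= max_gap
    }
    # connected components by repeated multiplication (transitive closure)
    reach <- adj
    repeat {
      nxt <- (reach %*% reach) > 0 | reach
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    comp <- rep(NA_integer_, n)
    cid <- 0L
    for (i in seq_len(n)) {
      if (is.na(comp[i])) { cid <- cid + 1L; comp[which(reach[i, ])] <- cid }
    }
    for (k in unique(comp)) {
      out[[length(out) + 1L]] <- sort(df$gene_id[idx[comp == k]])
    }
  }
  out[order(vapply(out, paste, character(1), collapse = ","))]
}

# brute-force oracle: enumerate every begin-to-end state path of a
# profile HMM emitting exactly the given residues and sum path
# probabilities (transition model: M->{M,I,D}, I->{M,I}, D->{M,D};
# inserts emit background)
enumerate_forward <- function(hmm, residues) {
  x <- strsplit(residues, "")[[1]]
  codes <- match(x, nlrforge:::AA20)
  L <- hmm$length
  tr <- hmm$transitions
  em <- hmm$match_emissions
  bg <- hmm$background
  total <- 0
  # state: (k = last match/delete index reached, type in M/I/D, i = residues emitted)
  recurse <- function(k, type, i, p) {
    if (k == L && type != "I") {
      # may exit, or go through I_L first
      if (i == length(x)) total <<- total + p * tr[L + 1, type, "M"]
      # continue into I_L
      if (i < length(x)) {
        recurse(k, "I", i + 1, p * tr[L + 1, type, "I"] * bg[codes[i + 1]])
      }
      return(invisible())
    }
    if (k == L && type == "I") {
      if (i == length(x)) total <<- total + p * tr[L + 1, "I", "M"]
      if (i < length(x)) {
        recurse(k, "I", i + 1, p * tr[L + 1, "I", "I"] * bg[codes[i + 1]])
      }
      return(invisible())
    }
    idx <- k + 1  # transition table row for state index k
    if (type == "I") {
      # I_k -> M_{k+1} or I_k
      if (i < length(x)) {
        recurse(k + 1, "M", i + 1,
                p * tr[idx, "I", "M"] * em[k + 1, codes[i + 1]])
        recurse(k, "I", i + 1, p * tr[idx, "I", "I"] * bg[codes[i + 1]])
      }
      return(invisible())
    }
    # type M or D at index k (begin = M at k 0)
    if (i < length(x)) {
      recurse(k + 1, "M", i + 1,
              p * tr[idx, type, "M"] * em[k + 1, codes[i + 1]])
      if (type == "M" && k >= 1) {
        recurse(k, "I", i + 1, p * tr[idx, "M", "I"] * bg[codes[i + 1]])
      }
      if (k == 0) {
        recurse(k, "I", i + 1, p * tr[1, "M", "I"] * bg[codes[i + 1]])
      }
    }
    recurse(k + 1, "D", i, p * tr[idx, type, "D"])
  }
  recurse(0, "M", 0, 1)
  unname(total)
}


# exhaustive affine-gap global alignment oracle over all alignments of
# two short sequences (recursion over (i, j, state))
oracle_nw <- function(a, b, open = 10, ext = 1) {
  B <- nlrforge:::blosum62()
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- if (i == 0 && j == 0) {
      0
    } else {
      best <- -Inf
      if (i > 0 && j > 0) {
        best <- max(best, rec(i - 1, j - 1, "M") + B[ca[i], cb[j]])
      }
      if (i > 0) {
        prev <- rec(i - 1, j, "X")
        cost <- if (state == "X") ext else open + ext
        best <- max(best, prev - 0)  # placeholder, replaced below
      }
      best
    }
    res
  }
  # simpler: plain DP with three matrices
  n1 <- length(ca); n2 <- length(cb)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n1 + 1, n2 + 1)
  M[1, 1] <- 0
  for (i in 1:n1) X[i + 1, 1] <- -(open + i * ext)
  for (j in 1:n2) Y[1, j + 1] <- -(open + j * ext)
  for (i in 1:n1) for (j in 1:n2) {
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + B[ca[i], cb[j]]
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  max(M[n1 + 1, n2 + 1], X[n1 + 1, n2 + 1], Y[n1 + 1, n2 + 1])
}

align_score <- function(al) {
  # score of a pairwise alignment under BLOSUM62 with affine gaps
  B <- nlrforge:::blosum62()
  r1 <- strsplit(al$aligned[1], "")[[1]]
  r2 <- strsplit(al$aligned[2], "")[[1]]
  s <- 0; in1 <- FALSE; in2 <- FALSE
  for (k in seq_along(r1)) {
    if (r1[k] == "-") {
      s <- s - (if (in1) 1 else 11); in1 <- TRUE; in2 <- FALSE
    } else if (r2[k] == "-") {
      s <- s - (if (in2) 1 else 11); in2 <- TRUE; in1 <- FALSE
    } else {
      s <- s + B[r1[k], r2[k]]; in1 <- in2 <- FALSE
    }
  }
  s
}

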