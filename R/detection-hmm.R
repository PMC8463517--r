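# Profile hidden Markov model of a protein domain: build from an aligned
# block, score sequences by local Viterbi log-odds, forward algorithm for
# cross-checks. A deliberately small model (single-hit, match/insert/
# delete; insert states emit background) rather than a full Plan7.

#' Build a profile HMM from an aligned block
#'
#' Columns with at least 50% residues become match states; other columns
#' feed the flanking insert states. Emissions and transitions are
#' maximum-likelihood counts with Laplace +1 pseudocounts, so no
#' probability is zero. Insert states emit the background distribution.
#'
#' @param msa Aligned block: tibble with columns `id` and `aligned`
#'   (equal-length gapped rows, `-` for gaps), as produced by
#'   [progressive_align()].
#' @param match_threshold Minimum non-gap fraction for a match column
#'   (default 0.5).
#' @param background Amino-acid background (default uniform).
#' @return An `nlr_phmm` object: `length`, `match_emissions`
#'   (L x 20), `transitions` (per-state 3x3 among M/I/D), `background`.
#' @export
build_profile_hmm <- function(msa, match_threshold = 0.5,
                              background = stats::setNames(rep(1 / 20, 20), AA20)) {
  stopifnot(all(c("id", "aligned") %in% names(msa)))
  if (nrow(msa) < 5) stop("need at least 5 aligned rows")
  rows <- toupper(msa$aligned)
  W <- unique(nchar(rows))
  if (length(W) != 1L) stop("aligned rows must have equal length")
  chmat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  isres <- chmat != "-" & chmat != "."
  match_col <- colMeans(isres) >= match_threshold
  L <- sum(match_col)
  if (L == 0L) stop("no match columns at this threshold")

  bg <- background / sum(background)
  emis <- matrix(1, nrow = L, ncol = 20, dimnames = list(NULL, AA20))  # Laplace
  # transitions[k+1, from, to]: from state index k = 0..L (0 = begin),
  # from in {M,I,D} (begin counts as M), to in {M,I,D} ("M"/"D" at k = L
  # mean the end state)
  trans <- array(1, dim = c(L + 1L, 3L, 3L),
                 dimnames = list(NULL, c("M", "I", "D"), c("M", "I", "D")))
  # neither I->D nor D->I transitions exist in this model (Plan7-style)
  trans[, "I", "D"] <- 0
  trans[, "D", "I"] <- 0

  colstate <- ifelse(match_col, "match", "insert")
  mindex <- cumsum(match_col)  # match-state index of each match column

  for (r in seq_len(nrow(chmat))) {
    k <- 0L; from <- "M"
    for (j in seq_len(W)) {
      ch <- chmat[r, j]
      if (colstate[j] == "match") {
        if (isres[r, j]) {
          a <- match(ch, AA20)
          if (!is.na(a)) emis[mindex[j], a] <- emis[mindex[j], a] + 1
          trans[k + 1L, from, "M"] <- trans[k + 1L, from, "M"] + 1
          k <- mindex[j]; from <- "M"
        } else {
          trans[k + 1L, from, "D"] <- trans[k + 1L, from, "D"] + 1
          k <- mindex[j]; from <- "D"
        }
      } else if (isres[r, j]) {
        # an insert residue straight after a delete has no legal path
        # (no D->I); leave it uncounted rather than fabricate one
        if (from != "D") {
          trans[k + 1L, from, "I"] <- trans[k + 1L, from, "I"] + 1
          from <- "I"
        }
      }
    }
    trans[k + 1L, from, "M"] <- trans[k + 1L, from, "M"] + 1  # exit to end
  }

  emis <- emis / rowSums(emis)
  for (k in seq_len(L + 1L)) {
    for (f in 1:3) {
      s <- sum(trans[k, f, ])
      trans[k, f, ] <- trans[k, f, ] / s
    }
  }
  structure(list(length = L, match_emissions = emis, transitions = trans,
                 background = bg),
            class = "nlr_phmm")
}

#' @export
print.nlr_phmm <- function(x, ...) {
  cat("<nlr_phmm> ", x$length, " match states\n", sep = "")
  invisible(x)
}

# local Viterbi log-odds (bits) with free flanking; returns score and the
# matched region of the sequence (0-based half-open)
phmm_viterbi_local <- function(hmm, residues) {
  x <- aa_encode(residues)
  n <- length(x)
  L <- hmm$length
  if (n == 0L) return(list(score = -Inf, start = 0L, end = 0L))
  lo_e <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  lt <- log2(hmm$transitions)
  NEG <- -1e30

  VM <- matrix(NEG, nrow = L, ncol = n)
  VI <- matrix(NEG, nrow = L, ncol = n)
  VD <- matrix(NEG, nrow = L, ncol = n)
  startM <- matrix(0L, nrow = L, ncol = n)  # sequence start of local path
  startI <- matrix(0L, nrow = L, ncol = n)
  startD <- matrix(0L, nrow = L, ncol = n)

  escore <- function(k, i) if (is.na(x[i])) 0 else lo_e[k, x[i]]

  for (i in seq_len(n)) {
    for (k in seq_len(L)) {
      # M: free entry (score 0) or continue from k-1 at i-1
      best <- 0; st <- i  # fresh entry starting at residue i
      if (k > 1L && i > 1L) {
        cM <- VM[k - 1L, i - 1L] + lt[k, "M", "M"]
        cI <- VI[k - 1L, i - 1L] + lt[k, "I", "M"]
        cD <- VD[k - 1L, i - 1L] + lt[k, "D", "M"]
        if (cM > best) { best <- cM; st <- startM[k - 1L, i - 1L] }
        if (cI > best) { best <- cI; st <- startI[k - 1L, i - 1L] }
        if (cD > best) { best <- cD; st <- startD[k - 1L, i - 1L] }
      }
      VM[k, i] <- best + escore(k, i); startM[k, i] <- st

      # I_k: insert after match k (emits background, log-odds 0)
      if (i > 1L) {
        cM <- VM[k, i - 1L] + lt[k + 1L, "M", "I"]
        cI <- VI[k, i - 1L] + lt[k + 1L, "I", "I"]
        if (cM >= cI) { VI[k, i] <- cM; startI[k, i] <- startM[k, i - 1L] }
        else          { VI[k, i] <- cI; startI[k, i] <- startI[k, i - 1L] }
      }

      # D_k
      if (k > 1L) {
        cM <- VM[k - 1L, i] + lt[k, "M", "D"]
        cD <- VD[k - 1L, i] + lt[k, "D", "D"]
        if (cM >= cD) { VD[k, i] <- cM; startD[k, i] <- startM[k - 1L, i] }
        else          { VD[k, i] <- cD; startD[k, i] <- startD[k - 1L, i] }
      }
    }
  }
  bi <- which.max(apply(VM, 2, max))
  bk <- which.max(VM[, bi])
  # uniform entry/exit over the L match states: charge 2 log2(L) so
  # chance runs on long random sequences stay below threshold
  list(score = VM[bk, bi] - 2 * log2(L), start = startM[bk, bi] - 1L, end = bi)
}

#' Score a protein sequence against a profile HMM
#'
#' Local Viterbi in log space with free flanking residues; the score is
#' the log2 odds of the best path versus the background null. Scores of
#' 10 bits or more are treated as confident domain hits by the detection
#' cascade (configurable there).
#'
#' @param hmm An `nlr_phmm` from [build_profile_hmm()].
#' @param residues A protein string, or a tibble with `id`/`residues`.
#' @return Numeric score(s) in bits.
#' @export
score_profile_hmm <- function(hmm, residues) {
  if (is.data.frame(residues)) {
    return(vapply(residues$residues,
                  function(r) phmm_viterbi_local(hmm, r)$score, numeric(1),
                  USE.NAMES = FALSE))
  }
  phmm_viterbi_local(hmm, residues)$score
}

#' Forward likelihood of a sequence under a profile HMM
#'
#' Sums over all state paths. `mode = "global"` returns the probability
#' that the model emits exactly the given sequence (begin-to-end path),
#' the quantity an exhaustive path enumeration computes; `mode = "local"`
#' returns the forward log2-odds with free flanking, an upper bound on
#' the local Viterbi score.
#'
#' @param hmm An `nlr_phmm`.
#' @param residues Protein string.
#' @param mode `"global"` or `"local"`.
#' @return Probability (global) or bits (local).
#' @export
forward_profile_hmm <- function(hmm, residues, mode = c("global", "local")) {
  mode <- match.arg(mode)
  x <- aa_encode(residues)
  n <- length(x)
  L <- hmm$length
  lse <- function(v) { v <- v[is.finite(v)]; if (!length(v)) return(-Inf)
    m <- max(v); m + log(sum(exp(v - m))) }

  if (mode == "global") {
    le <- log(hmm$match_emissions)
    lbg <- log(hmm$background)
    lt <- log(hmm$transitions)
    NEG <- -Inf
    # FM[k, i]: log P(prefix x_1..i, in M_k); FD silent; FI[k, i]
    FM <- matrix(NEG, L, n + 1L); FI <- matrix(NEG, L + 1L, n + 1L)
    FD <- matrix(NEG, L, n + 1L)
    # i index 1 = zero residues consumed
    # delete chain from begin
    for (i in 1L:(n + 1L)) {
      for (k in seq_len(L)) {
        if (i > 1L) {
          em <- if (is.na(x[i - 1L])) lbg[1] * 0 + log(1 / 20) else le[k, x[i - 1L]]
          prev <- if (k == 1L) {
            # from begin (state index 0): direct M, or via I_0
            c(if (i == 2L) lt[1L, "M", "M"] else NEG,
              FI[1L, i - 1L] + lt[1L, "I", "M"])
          } else {
            c(FM[k - 1L, i - 1L] + lt[k, "M", "M"],
              FI[k, i - 1L] + lt[k, "I", "M"],
              FD[k - 1L, i - 1L] + lt[k, "D", "M"])
          }
          FM[k, i] <- lse(prev) + em
        }
        # D_k
        prevd <- if (k == 1L) {
          if (i == 1L) lt[1L, "M", "D"] else NEG
        } else {
          lse(c(FM[k - 1L, i] + lt[k, "M", "D"],
                FD[k - 1L, i] + lt[k, "D", "D"]))
        }
        FD[k, i] <- prevd
      }
      # insert states I_0..I_L (FI row k+1 = I_k)
      if (i > 1L) {
        for (k in 0L:L) {
          em <- if (is.na(x[i - 1L])) log(1 / 20) else lbg[x[i - 1L]]
          prev <- if (k == 0L) {
            c(if (i == 2L) lt[1L, "M", "I"] else NEG,
              FI[1L, i - 1L] + lt[1L, "I", "I"])
          } else {
            c(FM[k, i - 1L] + lt[k + 1L, "M", "I"],
              FI[k + 1L, i - 1L] + lt[k + 1L, "I", "I"])
          }
          FI[k + 1L, i] <- lse(prev) + em
        }
      }
    }
    fin <- lse(c(FM[L, n + 1L] + lt[L + 1L, "M", "M"],
                 FD[L, n + 1L] + lt[L + 1L, "D", "M"],
                 FI[L + 1L, n + 1L] + lt[L + 1L, "I", "M"]))
    return(exp(fin))
  }

  # local forward log-odds (bits): same recursion as Viterbi with logsumexp
  lo_e <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  lt <- log2(hmm$transitions)
  lse2 <- function(v) { v <- v[v > -1e29]; if (!length(v)) return(-1e30)
    m <- max(v); m + log2(sum(2^(v - m))) }
  NEG <- -1e30
  VM <- matrix(NEG, L, n); VI <- matrix(NEG, L, n); VD <- matrix(NEG, L, n)
  for (i in seq_len(n)) {
    for (k in seq_len(L)) {
      inc <- 0  # free entry
      if (k > 1L && i > 1L) {
        inc <- lse2(c(0,
                      VM[k - 1L, i - 1L] + lt[k, "M", "M"],
                      VI[k - 1L, i - 1L] + lt[k, "I", "M"],
                      VD[k - 1L, i - 1L] + lt[k, "D", "M"]))
      }
      e <- if (is.na(x[i])) 0 else lo_e[k, x[i]]
      VM[k, i] <- inc + e
      if (i > 1L) {
        VI[k, i] <- lse2(c(VM[k, i - 1L] + lt[k + 1L, "M", "I"],
                           VI[k, i - 1L] + lt[k + 1L, "I", "I"]))
      }
      if (k > 1L) {
        VD[k, i] <- lse2(c(VM[k - 1L, i] + lt[k, "M", "D"],
                           VD[k - 1L, i] + lt[k, "D", "D"]))
      }
    }
  }
  lse2(as.vector(VM)) - 2 * log2(L)
}
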