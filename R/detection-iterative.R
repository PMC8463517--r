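# Iterative PSSM homology search: seeded Smith-Waterman rounds against a
# protein database, Karlin-Altschul E-values, and PSSM refinement from
# accumulated hits (the reiterative expansion stage of the detection
# cascade).

blosum62 <- function() {
  if (is.null(the$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the$blosum62 <- e$BLOSUM62[AA20, AA20]
  }
  the$blosum62
}

# q(b | a): BLOSUM62 conditional target frequencies (half-bit matrix,
# s_ab = 2 log2(q_ab / p_a p_b) => q(b|a) proportional to p_b 2^(s/2))
blosum62_conditional <- function() {
  if (is.null(the$b62_cond)) {
    B <- blosum62()
    bg <- rep(1 / 20, 20)
    Q <- sweep(2^(B / 2), 2, bg, "*")
    the$b62_cond <- Q / rowSums(Q)
  }
  the$b62_cond
}

# integer codes 1..20 for AA20, 21 for any other symbol (scores 0)
aa_encode21 <- function(x) {
  m <- match(strsplit(toupper(x), "", fixed = TRUE)[[1]], AA20)
  m[is.na(m)] <- 21L
  m
}

# position profile (n x 21) from a residue-score matrix and an encoded query
profile_from_matrix <- function(scoremat, qcodes) {
  P <- cbind(scoremat, 0)[qcodes, , drop = FALSE]
  P[qcodes == 21L, ] <- 0
  P
}

#' Smith-Waterman scores of a query against a sequence database
#'
#' Affine-gap local alignment (default BLOSUM62, gap open 11 / extend 1,
#' BLAST conventions: a gap of length k costs open + k * extend).
#'
#' @param query Protein string.
#' @param database Tibble of protein sequences (`id`, `residues`).
#' @param gap_open,gap_ext Gap penalties.
#' @return Numeric vector of optimal local scores, one per database row.
#' @export
sw_scores <- function(query, database, gap_open = 11, gap_ext = 1) {
  prof <- profile_from_matrix(blosum62(), aa_encode21(query))
  seqs <- lapply(database$residues, aa_encode21)
  .batch_local_scores_cpp(prof, seqs, gap_open, gap_ext)
}

#' Calibrate Karlin-Altschul parameters for the local-alignment scorer
#'
#' Fits the Gumbel law of optimal local scores from seeded random
#' alignments (uniform residue background) by moment matching:
#' \eqn{\lambda = \pi / (\sigma\sqrt 6)}, \eqn{\mu = \bar s - \gamma/\lambda},
#' \eqn{K = e^{\lambda\mu} / (m n)}. The fit is cached per scoring system.
#'
#' @param n_pairs Number of random sequence pairs (default 2000).
#' @param len Length of the random sequences (default 100).
#' @param gap_open,gap_ext Gap penalties of the scorer being calibrated.
#' @param seed Seed for the random draws.
#' @return List with `lambda` and `K`.
#' @export
calibrate_karlin_altschul <- function(n_pairs = 2000, len = 100,
                                      gap_open = 11, gap_ext = 1, seed = 1) {
  key <- paste("ka", n_pairs, len, gap_open, gap_ext, seed, sep = "_")
  if (!is.null(the[[key]])) return(the[[key]])
  set.seed(seed)
  B <- blosum62()
  scores <- numeric(n_pairs)
  chunk <- 50L
  i <- 1L
  while (i <= n_pairs) {
    q <- sample.int(20L, len, replace = TRUE)
    prof <- profile_from_matrix(B, q)
    nt <- min(chunk, n_pairs - i + 1L)
    targs <- lapply(seq_len(nt), function(z) sample.int(20L, len, replace = TRUE))
    scores[i:(i + nt - 1L)] <- .batch_local_scores_cpp(prof, targs, gap_open, gap_ext)
    i <- i + nt
  }
  lambda <- pi / (stats::sd(scores) * sqrt(6))
  mu <- mean(scores) - 0.5772156649 / lambda
  K <- exp(lambda * mu) / (len * len)
  the[[key]] <- list(lambda = lambda, K = K)
  the[[key]]
}

ka_evalue <- function(score, m, n, ka) ka$K * m * n * exp(-ka$lambda * score)

# build a half-bit PSSM for a query from locally aligned hit sequences:
# observed residue frequencies at each query position mixed half-and-half
# with BLOSUM62 conditional target frequencies of the query residue
build_pssm <- function(query, hit_residues, gap_open = 11, gap_ext = 1,
                       alpha = 0.5) {
  qc <- aa_encode21(query)
  nq <- length(qc)
  counts <- matrix(0, nrow = nq, ncol = 20)
  # the query itself always contributes
  std <- qc <= 20L
  counts[cbind(which(std), qc[std])] <- 1
  B21 <- rbind(cbind(blosum62(), 0), 0)  # 21x21, non-standard symbols score 0
  for (h in hit_residues) {
    hc <- aa_encode21(h)
    S <- B21[qc, hc, drop = FALSE]
    al <- .affine_align_cpp(S, gap_open, gap_ext, 1L, TRUE)
    p <- al$path
    if (nrow(p) == 0L) next
    both <- p[, 1] > 0 & p[, 2] > 0
    qi <- p[both, 1]; ti <- hc[p[both, 2]]
    keep <- ti <= 20L
    idx <- cbind(qi[keep], ti[keep])
    for (r in seq_len(nrow(idx))) counts[idx[r, 1], idx[r, 2]] <-
        counts[idx[r, 1], idx[r, 2]] + 1
  }
  freq <- counts / pmax(rowSums(counts), 1)
  cond <- blosum62_conditional()
  pseudo <- matrix(1 / 20, nrow = nq, ncol = 20)
  pseudo[std, ] <- cond[qc[std], , drop = FALSE]
  q <- (1 - alpha) * freq + alpha * pseudo
  q[rowSums(counts) == 0, ] <- pseudo[rowSums(counts) == 0, ]
  bg <- rep(1 / 20, 20)
  pssm <- 2 * log2(sweep(pmax(q, 1e-6), 2, bg, "/"))  # half-bit scale
  pssm
}

#' Iterative PSSM homology search
#'
#' Round 0 scores the database against each query by Smith-Waterman
#' (BLOSUM62, affine gaps); hits passing the E-value cutoff are aligned
#' back to the query to estimate a position-specific scoring matrix
#' (half-bit log-odds with pseudocount mixing toward BLOSUM62 target
#' frequencies), and later rounds rescan the database with the PSSM,
#' picking up homologs linked only through intermediates. Iteration stops
#' when a round adds no new hits or after `max_iter` PSSM rounds.
#'
#' @param queries Tibble of protein queries (`id`, `residues`).
#' @param database Tibble of protein sequences (`id`, `residues`).
#' @param evalue_cutoff Inclusion threshold (default 1e-10).
#' @param max_iter Maximum number of PSSM rounds after round 0 (default 5);
#'   0 gives the plain Smith-Waterman hit set.
#' @param gap_open,gap_ext Gap penalties (default 11 / 1).
#' @param ka Karlin-Altschul parameters (default:
#'   [calibrate_karlin_altschul()] with its defaults).
#' @return Tibble of detection hits: `seq_id`, `stage = "iterative"`,
#'   `score_bits`, `e_value`, `round` (the round each hit first appeared
#'   in), best E-value per database sequence.
#' @export
iterative_pssm_search <- function(queries, database, evalue_cutoff = 1e-10,
                                  max_iter = 5, gap_open = 11, gap_ext = 1,
                                  ka = calibrate_karlin_altschul(
                                    gap_open = gap_open, gap_ext = gap_ext)) {
  if (evalue_cutoff <= 0) stop("evalue_cutoff must be positive")
  if (nrow(database) == 0L) stop("empty database")
  db_codes <- lapply(database$residues, aa_encode21)
  n_db <- sum(nchar(database$residues))

  score_round <- function(prof) {
    s <- .batch_local_scores_cpp(prof, db_codes, gap_open, gap_ext)
    e <- ka_evalue(s, nrow(prof), n_db, ka)
    tibble::tibble(seq_id = database$id, score = s, e_value = e)
  }

  best <- NULL
  add_hits <- function(best, new, round) {
    new <- dplyr::mutate(dplyr::filter(new, .data$e_value <= evalue_cutoff),
                         round = round)
    if (is.null(best)) return(new)
    dplyr::bind_rows(best, new) %>%
      dplyr::group_by(.data$seq_id) %>%
      dplyr::slice_min(.data$e_value, n = 1, with_ties = FALSE) %>%
      dplyr::ungroup()
  }

  # round 0: plain BLOSUM62 scan per query
  for (qi in seq_len(nrow(queries))) {
    prof <- profile_from_matrix(blosum62(), aa_encode21(queries$residues[qi]))
    best <- add_hits(best, score_round(prof), 0L)
  }

  if (max_iter > 0L) {
    for (it in seq_len(max_iter)) {
      before <- sort(best$seq_id)
      for (qi in seq_len(nrow(queries))) {
        hit_res <- database$residues[database$id %in% best$seq_id]
        pssm <- build_pssm(queries$residues[qi], hit_res,
                           gap_open = gap_open, gap_ext = gap_ext)
        prof <- cbind(pssm, 0)
        best <- add_hits(best, score_round(prof), it)
      }
      if (identical(sort(best$seq_id), before)) break
    }
  }

  if (is.null(best) || nrow(best) == 0L) {
    return(tibble::tibble(seq_id = character(), stage = character(),
                          score_bits = numeric(), e_value = numeric(),
                          round = integer()))
  }
  best %>%
    dplyr::transmute(seq_id = .data$seq_id, stage = "iterative",
                     score_bits = .data$score / 2, e_value = .data$e_value,
                     round = .data$round) %>%
    dplyr::arrange(.data$e_value)
}

#' Union of detection-stage hit tables
#'
#' The detection cascade's final candidate set is the union of motif,
#' profile-HMM and iterative hits, deduplicated by sequence id (a
#' sequence found by several stages keeps each stage's record, but
#' appears once in the candidate list).
#'
#' @param ... Hit tibbles with at least `seq_id` and `stage`.
#' @return Tibble with one row per (seq_id, stage) and an attribute-free
#'   `candidates` column view via `unique(out$seq_id)`.
#' @export
combine_detection_hits <- function(...) {
  tabs <- purrr::compact(list(...))
  if (!length(tabs)) return(tibble::tibble(seq_id = character(), stage = character()))
  dplyr::bind_rows(tabs) %>%
    dplyr::distinct(.data$seq_id, .data$stage, .keep_all = TRUE) %>%
    dplyr::arrange(.data$seq_id, .data$stage)
}
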