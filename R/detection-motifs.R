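# Motif elicitation (EM over the one-occurrence-per-sequence model) and
# MAST-style scanning with exact score-distribution p-values.

# integer-encode a protein string over AA20; X, *, gaps and other
# non-standard symbols become NA and score as background (log-odds 0)
aa_encode <- function(x) {
  m <- match(strsplit(x, "", fixed = TRUE)[[1]], AA20)
  m
}

#' Elicit ungapped motifs from reference NB-ARC domain sequences
#'
#' Expectation-maximisation over the OOPS model (one motif occurrence per
#' sequence): the E-step computes a posterior over start positions, the
#' M-step re-estimates the position weight matrix with a +`pseudocount`
#' per cell. Several seeded restarts are run and the best log-likelihood
#' wins; after each motif is reported its occurrences are masked so the
#' next motif must explain different signal.
#'
#' @param reference Tibble of protein sequences (`id`, `residues`), at
#'   least 5, each at least `width` residues.
#' @param n_motifs Number of motifs to elicit (default 5).
#' @param width Motif width in residues (default 12, minimum 4).
#' @param seed Integer seed driving restarts.
#' @param n_restarts EM restarts per motif (default 10); ties in final
#'   log-likelihood break toward the lower restart index.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` (default 1e-6) or after `max_iter`
#'   (default 200) iterations.
#' @param pseudocount Added to each PWM cell before normalisation.
#' @param background Amino-acid background distribution (default uniform).
#' @return A list of `nlr_motif` objects (fields `id`, `width`, `prob`,
#'   `pwm` in log2-odds bits, `consensus`, `background`).
#' @export
elicit_motifs <- function(reference, n_motifs = 5, width = 12, seed = 1,
                          n_restarts = 10, max_iter = 200, tol = 1e-6,
                          pseudocount = 0.01,
                          background = stats::setNames(rep(1 / 20, 20), AA20)) {
  stopifnot(width >= 4, n_motifs >= 1)
  if (nrow(reference) < 5) stop("need at least 5 reference sequences")
  lens <- nchar(reference$residues)
  if (any(lens < width)) stop("all reference sequences must be at least `width` long")
  if (n_motifs * width > min(lens)) {
    stop("n_motifs * width exceeds the shortest reference sequence")
  }
  seqs <- lapply(reference$residues, aa_encode)
  masked <- lapply(lens, function(n) rep(FALSE, n))
  bg <- background / sum(background)

  motifs <- vector("list", n_motifs)
  for (m in seq_len(n_motifs)) {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- oops_em(seqs, masked, width, bg,
                     seed = seed + 1000L * (m - 1L) + r,
                     max_iter = max_iter, tol = tol, pseudocount = pseudocount)
      if (is.null(best) || fit$loglik > best$loglik + 1e-12) best <- fit
    }
    if (is.null(best)) stop("EM failed: no unmasked windows remain")
    # mask MAP occurrences of this motif
    for (i in seq_along(seqs)) {
      j <- best$map_start[i]
      if (!is.na(j)) masked[[i]][j:(j + width - 1L)] <- TRUE
    }
    prob <- best$prob
    pwm <- log2(sweep(prob, 2, bg, "/"))
    consensus <- paste(AA20[apply(prob, 1, which.max)], collapse = "")
    motifs[[m]] <- structure(
      list(id = paste0("motif_", m), width = width, prob = prob, pwm = pwm,
           consensus = consensus, background = bg, loglik = best$loglik),
      class = "nlr_motif")
  }
  motifs
}

#' @export
print.nlr_motif <- function(x, ...) {
  cat("<nlr_motif> ", x$id, "  width ", x$width, "  consensus ", x$consensus,
      "\n", sep = "")
  invisible(x)
}

# one EM run over unmasked windows; returns prob (w x 20), loglik,
# MAP start per sequence (NA if no valid window)
oops_em <- function(seqs, masked, width, bg, seed, max_iter, tol, pseudocount) {
  set.seed(seed)
  n <- length(seqs)
  valid_starts <- lapply(seq_len(n), function(i) {
    L <- length(seqs[[i]])
    js <- seq_len(L - width + 1L)
    ok <- vapply(js, function(j) !any(masked[[i]][j:(j + width - 1L)]), logical(1))
    js[ok]
  })
  usable <- which(lengths(valid_starts) > 0L)
  if (length(usable) == 0L) stop("no unmasked windows available")

  # init from a random window: consensus letter at 0.5
  i0 <- sample(usable, 1L)
  j0 <- sample(valid_starts[[i0]], 1L)
  win <- seqs[[i0]][j0:(j0 + width - 1L)]
  prob <- matrix(0.5 / 19, nrow = width, ncol = 20)
  for (k in seq_len(width)) {
    if (!is.na(win[k])) prob[k, win[k]] <- 0.5 else prob[k, ] <- 1 / 20
  }

  ll_old <- -Inf
  map_start <- rep(NA_integer_, n)
  for (iter in seq_len(max_iter)) {
    lratio <- log(sweep(prob, 2, bg, "/"))   # width x 20
    counts <- matrix(0, nrow = width, ncol = 20)
    ll <- 0
    for (i in usable) {
      x <- seqs[[i]]
      js <- valid_starts[[i]]
      idx <- outer(0:(width - 1L), js, "+") + 0L  # width x nj, 0-based offsets
      letters <- matrix(x[idx + 0L], nrow = width)
      lsc <- matrix(0, nrow = width, ncol = length(js))
      std <- !is.na(letters)
      lsc[std] <- lratio[cbind(row(letters)[std], letters[std])]
      s <- colSums(lsc)
      mx <- max(s)
      w <- exp(s - mx)
      z <- w / sum(w)
      ll <- ll + mx + log(mean(w))
      map_start[i] <- js[which.max(z)]
      # accumulate expected counts
      for (k in seq_len(width)) {
        lk <- letters[k, ]
        okk <- !is.na(lk)
        if (any(okk)) {
          tz <- tapply(z[okk], lk[okk], sum)
          counts[k, as.integer(names(tz))] <- counts[k, as.integer(names(tz))] + tz
        }
      }
    }
    prob <- counts + pseudocount / 20  # total pseudocount mass per column
    prob <- prob / rowSums(prob)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { ll_old <- ll; break }
    ll_old <- ll
  }
  list(prob = prob, loglik = ll_old, map_start = map_start)
}

# exact null tail of the integer-rounded PWM score distribution under the
# motif background: returns function(score_int) -> P(S >= score_int)
pwm_null_tail <- function(motif, scale = 10) {
  S <- round(motif$pwm * scale)
  bg <- motif$background
  # convolve per-position score distributions, starting from point mass at 0
  dist <- c(1); off <- 0L
  for (k in seq_len(nrow(S))) {
    sc <- S[k, ]
    newlo <- off + min(sc); newhi <- off + length(dist) - 1L + max(sc)
    nd <- rep(0, newhi - newlo + 1L)
    for (a in 1:20) {
      sh <- sc[a] + off - newlo
      idx <- seq_along(dist) + sh
      nd[idx] <- nd[idx] + dist * bg[a]
    }
    dist <- nd; off <- newlo
  }
  tail_cum <- rev(cumsum(rev(dist)))
  support_min <- off
  function(s_int) {
    i <- s_int - support_min + 1L
    if (i <= 1L) return(1)
    if (i > length(tail_cum)) return(0)
    unname(tail_cum[i])
  }
}

# best-scoring window of a motif on an encoded sequence. Non-standard
# symbols (X, *, gaps) take the background-expected column score so that
# stop-rich reading frames stay null-neutral instead of outscoring the
# (very negative) typical random window.
best_motif_window <- function(S, x, bg = rep(1 / 20, 20)) {
  w <- nrow(S)
  n <- length(x)
  if (n < w) return(NULL)
  expcol <- as.numeric(S %*% bg)
  js <- seq_len(n - w + 1L)
  idx <- outer(0:(w - 1L), js, "+")
  letters <- matrix(x[idx], nrow = w)
  sc <- matrix(rep(expcol, length(js)), nrow = w)
  std <- !is.na(letters)
  sc[std] <- S[cbind(row(letters)[std], letters[std])]
  s <- colSums(sc)
  j <- which.max(s)
  list(start = js[j] - 1L, score_int = floor(s[j]))
}

# QFAST combination of m independent p-values whose product is p
qfast_combine <- function(pvals) {
  pvals <- pmin(pmax(pvals, 1e-300), 1)
  m <- length(pvals)
  lp <- sum(log(pvals))
  if (m == 1L) return(exp(lp))
  k <- 0:(m - 1)
  # p * sum (-ln p)^k / k!  computed in log space for stability
  terms <- k * log(pmax(-lp, 1e-300)) - lgamma(k + 1)
  exp(lp + max(terms) + log(sum(exp(terms - max(terms)))))
}

#' Scan peptides with a motif set (MAST-style)
#'
#' Each motif's best-scoring window per sequence gets an exact p-value
#' from the dynamic-programming convolution of its integer-rounded PWM
#' score distribution under the background; per-sequence motif p-values
#' are combined with the QFAST product formula and converted to E-values
#' against the database size.
#'
#' @param peptides Tibble of protein sequences (`id`, `residues`) or a
#'   six-frame translation table (`source_id`, `peptide`); frames are
#'   scanned separately and aggregated to their source transcript.
#' @param motifs List of `nlr_motif` objects from [elicit_motifs()].
#' @param evalue_threshold Report sequences with combined E-value at or
#'   below this (default 10, the conventional report threshold).
#' @param scale Integer score granularity: scores are rounded to
#'   1/`scale` bits (default 10).
#' @return Tibble of detection hits (`seq_id`, `stage = "motif"`,
#'   `score_bits`, `p_comb`, `e_value`), one row per passing sequence,
#'   with the per-motif best windows of all scanned sequences in
#'   `attr(, "motif_hits")` (`motif_id`, `seq_id`, `start` 0-based,
#'   `score_bits`, `p_value`).
#' @export
scan_motifs <- function(peptides, motifs, evalue_threshold = 10, scale = 10) {
  if (length(motifs) == 0L) stop("no motifs")
  units <- normalize_peptides(peptides)
  n_db <- dplyr::n_distinct(units$seq_id)
  tails <- lapply(motifs, pwm_null_tail, scale = scale)
  Ss <- lapply(motifs, function(m) round(m$pwm * scale))

  skipped <- character(0)
  per_unit <- purrr::map_dfr(seq_len(nrow(units)), function(i) {
    x <- aa_encode(units$peptide[i])
    rows <- purrr::map_dfr(seq_along(motifs), function(mi) {
      bw <- best_motif_window(Ss[[mi]], x, motifs[[mi]]$background)
      if (is.null(bw)) return(tibble::tibble())
      # position p-value of the best window, corrected for the number of
      # windows scanned (p_seq = 1 - (1 - p)^m, computed stably)
      p_pos <- tails[[mi]](bw$score_int)
      m_win <- length(x) - motifs[[mi]]$width + 1L
      p_seq <- -expm1(m_win * log1p(-min(p_pos, 1 - 1e-16)))
      tibble::tibble(motif_id = motifs[[mi]]$id,
                     seq_id = units$seq_id[i],
                     unit = i,
                     start = bw$start,
                     score_bits = bw$score_int / scale,
                     p_value = max(p_seq, 1e-300))
    })
    if (nrow(rows) == 0L) skipped <<- c(skipped, units$seq_id[i])
    rows
  })
  if (length(skipped)) {
    message("skipped ", length(unique(skipped)),
            " sequence(s) shorter than every motif")
  }
  if (nrow(per_unit) == 0L) {
    out <- tibble::tibble(seq_id = character(), stage = character(),
                          score_bits = numeric(), p_comb = numeric(),
                          e_value = numeric())
    attr(out, "motif_hits") <- per_unit
    return(out)
  }

  combined <- per_unit %>%
    dplyr::group_by(.data$seq_id, .data$unit) %>%
    dplyr::summarise(score_bits = sum(.data$score_bits),
                     p_comb = qfast_combine(.data$p_value),
                     .groups = "drop") %>%
    dplyr::group_by(.data$seq_id) %>%
    dplyr::slice_min(.data$p_comb, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(stage = "motif", e_value = .data$p_comb * n_db) %>%
    dplyr::select("seq_id", "stage", "score_bits", "p_comb", "e_value")

  hits <- dplyr::filter(combined, .data$e_value <= evalue_threshold) %>%
    dplyr::arrange(.data$e_value)
  attr(hits, "motif_hits") <- dplyr::select(per_unit, -"unit")
  hits
}

#' Per-motif window hits attached to a [scan_motifs()] result
#' @param x Result of [scan_motifs()].
#' @return Tibble of per-motif best windows.
#' @export
motif_hits <- function(x) attr(x, "motif_hits")

# accept either (id, residues) protein tibble or a six-frame table
normalize_peptides <- function(peptides) {
  if (all(c("source_id", "peptide") %in% names(peptides))) {
    tibble::tibble(seq_id = peptides$source_id, peptide = peptides$peptide)
  } else if (all(c("id", "residues") %in% names(peptides))) {
    tibble::tibble(seq_id = peptides$id, peptide = peptides$residues)
  } else {
    stop("peptides must have columns id/residues or source_id/peptide")
  }
}
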