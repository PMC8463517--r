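# Domain detection on candidate proteins and classification into the
# CNL/TNL/RNL architecture taxonomy, plus repertoire summaries.

KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2)

CC_HYDROPHOBIC <- c("L", "I", "V", "M", "F", "A")

# merge overlapping/adjacent [start, end) intervals; keeps max score
merge_intervals <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$start), ]
  out <- df[1, ]
  for (i in 2:nrow(df)) {
    last <- nrow(out)
    if (df$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], df$end[i])
      out$score[last] <- max(out$score[last], df$score[i])
    } else {
      out <- rbind(out, df[i, ])
    }
  }
  out
}

#' Detect NLR-associated domains on a protein
#'
#' Profile-HMM domains (NB, TIR, RPW8, integrated domains) are called by
#' local Viterbi log-odds at or above `bits_threshold`. Coiled-coil (CC)
#' segments are called by heptad periodicity: a sliding window scores the
#' fraction of hydrophobic residues (L/I/V/M/F/A) at heptad positions a
#' and d. Leucine-rich repeats (LRR) are called from the density of the
#' LxxLxL structural signature, transmembrane (TM) segments by
#' Kyte-Doolittle mean hydropathy. Overlapping calls of the same kind are
#' merged.
#'
#' @param protein A protein string, or a one-row tibble with `residues`.
#' @param nb_profile `nlr_phmm` for the NB-ARC domain (optional).
#' @param nterm_profiles Named list of `nlr_phmm`s; names `TIR` and
#'   `RPW8` map to those kinds, any other name is treated as an
#'   integrated-domain (`ID`) profile of that name.
#' @param bits_threshold Profile-HMM call threshold (default 10 bits).
#' @param cc_window,cc_min_fraction CC caller: window length (default 28)
#'   and minimum a/d hydrophobic fraction (default 0.6).
#' @param lrr_min_matches,lrr_span LRR caller: minimum LxxLxL matches
#'   (default 3) within a span (default 90 residues).
#' @param tm_window,tm_threshold TM caller: window (default 19) and mean
#'   hydropathy threshold (default 1.8).
#' @return Tibble of domain annotations sorted by start: `kind`,
#'   `id_name` (NA except for integrated domains), `start`, `end`
#'   (0-based half-open), `score`. Empty tibble when nothing is found.
#' @export
detect_domains <- function(protein, nb_profile = NULL, nterm_profiles = list(),
                           bits_threshold = 10,
                           cc_window = 28, cc_min_fraction = 0.6,
                           lrr_min_matches = 3, lrr_span = 90,
                           tm_window = 19, tm_threshold = 1.8) {
  if (is.data.frame(protein)) protein <- protein$residues[[1]]
  protein <- toupper(protein)
  n <- nchar(protein)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  ann <- list()

  profile_call <- function(hmm, kind, id_name = NA_character_) {
    v <- phmm_viterbi_local(hmm, protein)
    if (is.finite(v$score) && v$score >= bits_threshold) {
      tibble::tibble(kind = kind, id_name = id_name,
                     start = v$start, end = v$end, score = v$score)
    } else NULL
  }
  if (!is.null(nb_profile)) ann$nb <- profile_call(nb_profile, "NB")
  for (nm in names(nterm_profiles)) {
    kind <- if (nm %in% c("TIR", "RPW8")) nm else "ID"
    idn <- if (kind == "ID") nm else NA_character_
    ann[[paste0("p_", nm)]] <- profile_call(nterm_profiles[[nm]], kind, idn)
  }

  # CC by heptad periodicity
  if (n >= cc_window) {
    ad <- which((0:(cc_window - 1)) %% 7 %in% c(0, 3))
    hyd <- chars %in% CC_HYDROPHOBIC
    starts <- seq_len(n - cc_window + 1L)
    frac <- vapply(starts, function(s) mean(hyd[s - 1L + ad]), numeric(1))
    hitw <- which(frac >= cc_min_fraction)
    if (length(hitw)) {
      cc <- tibble::tibble(kind = "CC", id_name = NA_character_,
                           start = hitw - 1L, end = hitw - 1L + cc_window,
                           score = frac[hitw])
      ann$cc <- merge_intervals(cc)
    }
  }

  # LRR by LxxLxL signature density (overlapping matches via lookahead)
  m <- gregexpr("(?=[LIVF]..[LIVF].[LIVF])", protein, perl = TRUE)[[1]]
  if (m[1] != -1L) {
    pos <- as.integer(m) - 1L  # 0-based signature starts
    regions <- list()
    for (i in seq_along(pos)) {
      inwin <- pos[pos >= pos[i] & pos < pos[i] + lrr_span]
      if (length(inwin) >= lrr_min_matches) {
        regions[[length(regions) + 1L]] <-
          tibble::tibble(kind = "LRR", id_name = NA_character_,
                         start = inwin[1], end = inwin[length(inwin)] + 6L,
                         score = length(inwin))
      }
    }
    if (length(regions)) ann$lrr <- merge_intervals(dplyr::bind_rows(regions))
  }

  # TM by Kyte-Doolittle hydropathy
  if (n >= tm_window) {
    kd <- KD_HYDROPATHY[chars]
    kd[is.na(kd)] <- 0
    csum <- cumsum(c(0, kd))
    starts <- seq_len(n - tm_window + 1L)
    means <- (csum[starts + tm_window] - csum[starts]) / tm_window
    hitw <- which(means > tm_threshold)
    if (length(hitw)) {
      tm <- tibble::tibble(kind = "TM", id_name = NA_character_,
                           start = hitw - 1L, end = hitw - 1L + tm_window,
                           score = means[hitw])
      ann$tm <- merge_intervals(tm)
    }
  }

  out <- dplyr::bind_rows(ann)
  if (nrow(out) == 0L) {
    return(tibble::tibble(kind = character(), id_name = character(),
                          start = integer(), end = integer(), score = numeric()))
  }
  # heptad windows inside another domain (L-rich LRR/TIR repeats mimic
  # coiled coils) are artefacts: drop CC calls overlapping a non-CC,
  # non-TM domain call by half or more of their length
  if (any(out$kind == "CC")) {
    other <- out[!out$kind %in% c("CC", "TM"), ]
    artefact <- vapply(seq_len(nrow(out)), function(i) {
      if (out$kind[i] != "CC" || nrow(other) == 0) return(FALSE)
      ov <- pmax(0, pmin(out$end[i], other$end) - pmax(out$start[i], other$start))
      max(ov) >= 0.5 * (out$end[i] - out$start[i])
    }, logical(1))
    out <- out[!artefact, ]
  }
  dplyr::arrange(out, .data$start)
}

# canonical N-to-C ordering used for partial labels
CORE_KIND_ORDER <- c("CC", "TIR", "RPW8", "NB", "LRR")

#' Classify a domain architecture
#'
#' A protein with both NB and LRR is full-length; its subclass follows
#' the N-terminal-most of TIR (TNL), RPW8 (RNL) or CC (CNL), and is NL
#' when no recognised N-terminal domain is present. Otherwise the label
#' is the hyphenated list of core domains present in N-to-C canonical
#' order (reproducing the partial classes CC-NB, CC-LRR, TIR-NB,
#' TIR-LRR, NB, TIR, LRR, RPW8). TM and integrated domains do not enter
#' the label. An empty architecture is `"unclassified"`.
#'
#' @param domains Tibble of domain annotations ([detect_domains()]
#'   output), or a character vector of kinds (then the canonical order
#'   stands in for positions).
#' @return Tibble with one row: `class_label`, `is_full_length`.
#' @export
classify_architecture <- function(domains) {
  if (is.character(domains)) {
    kinds <- domains
    starts <- match(kinds, CORE_KIND_ORDER)
  } else {
    kinds <- domains$kind
    starts <- domains$start
  }
  core <- kinds %in% CORE_KIND_ORDER
  kinds <- kinds[core]; starts <- starts[core]
  present <- unique(kinds)

  if (length(present) == 0L) {
    return(tibble::tibble(class_label = "unclassified", is_full_length = FALSE))
  }
  full <- all(c("NB", "LRR") %in% present)
  if (full) {
    nterm <- c("CC", "TIR", "RPW8")
    cand <- kinds %in% nterm
    label <- if (!any(cand)) "NL" else {
      first <- kinds[cand][which.min(starts[cand])]
      c(CC = "CNL", TIR = "TNL", RPW8 = "RNL")[[first]]
    }
    return(tibble::tibble(class_label = label, is_full_length = TRUE))
  }
  ord <- CORE_KIND_ORDER[CORE_KIND_ORDER %in% present]
  tibble::tibble(class_label = paste(ord, collapse = "-"), is_full_length = FALSE)
}

#' Annotate and classify a set of candidate proteins
#'
#' Runs [detect_domains()] and [classify_architecture()] over a protein
#' table and returns one record per protein that carries at least one
#' domain call (the curation rule: any candidate with a single or partial
#' NLR domain enters the record set).
#'
#' @param proteins Tibble (`id`, `residues`).
#' @param nb_profile,nterm_profiles,... Passed to [detect_domains()].
#' @param source Provenance label stored on each record (default
#'   `"transcriptome"`).
#' @return Tibble of NLR records: `gene_id`, `source`, `class_label`,
#'   `is_full_length`, `has_id`, `has_tm`, `n_domains`, and a `domains`
#'   list-column of per-protein annotation tibbles.
#' @export
annotate_nlrs <- function(proteins, nb_profile = NULL, nterm_profiles = list(),
                          source = "transcriptome", ...) {
  recs <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    dom <- detect_domains(proteins$residues[i], nb_profile, nterm_profiles, ...)
    cls <- classify_architecture(dom)
    tibble::tibble(gene_id = proteins$id[i], source = source,
                   class_label = cls$class_label,
                   is_full_length = cls$is_full_length,
                   has_id = any(dom$kind == "ID"),
                   has_tm = any(dom$kind == "TM"),
                   n_domains = nrow(dom),
                   domains = list(dom))
  })
  dplyr::filter(recs, .data$class_label != "unclassified")
}

#' Summarise an NLR repertoire
#'
#' Tabulates class counts and totals from a record table and/or published
#' per-accession counts, reproducing the layout of repertoire tables:
#' total, full-length and partial totals, per-accession mean (rounded
#' half-up) / min / max, percent full-length (rounded half-up), and the
#' share of source transcripts shorter than 700 bp.
#'
#' @param records Tibble of NLR records ([annotate_nlrs()]), or `NULL`
#'   when summarising printed counts only.
#' @param per_accession_counts Optional integer vector of per-accession
#'   repertoire sizes.
#' @param transcript_lengths Optional numeric vector of source transcript
#'   lengths (bp) for the short-transcript share.
#' @param n_full,total Optional explicit full-length and total counts
#'   (override values derived from `records`; used when summarising
#'   published tables).
#' @return An `nlr_repertoire` object; see [tidy.nlr_repertoire()] and
#'   [glance.nlr_repertoire()].
#' @export
summarize_repertoire <- function(records = NULL, per_accession_counts = NULL,
                                 transcript_lengths = NULL,
                                 n_full = NULL, total = NULL) {
  class_counts <- if (!is.null(records) && nrow(records) > 0) {
    dplyr::count(records, .data$class_label, .data$is_full_length, name = "n")
  } else {
    tibble::tibble(class_label = character(), is_full_length = logical(),
                   n = integer())
  }
  if (is.null(total)) {
    total <- if (!is.null(records)) nrow(records)
             else if (!is.null(per_accession_counts)) sum(per_accession_counts)
             else 0L
  }
  if (is.null(n_full)) {
    n_full <- if (!is.null(records) && nrow(records) > 0) sum(records$is_full_length)
              else NA_integer_
  }
  acc_mean <- acc_min <- acc_max <- NA_real_
  if (!is.null(per_accession_counts)) {
    acc_mean <- round_half_up(mean(per_accession_counts))
    acc_min <- min(per_accession_counts)
    acc_max <- max(per_accession_counts)
  }
  pct_full <- if (!is.na(n_full) && total > 0) round_half_up(100 * n_full / total)
              else NA_real_
  pct_short <- if (!is.null(transcript_lengths)) {
    100 * mean(transcript_lengths < 700)
  } else NA_real_
  structure(list(class_counts = class_counts, total = total,
                 total_full = n_full,
                 total_partial = if (is.na(n_full)) NA_integer_ else total - n_full,
                 accession_mean = acc_mean, accession_min = acc_min,
                 accession_max = acc_max, percent_full = pct_full,
                 percent_short_transcripts = pct_short),
            class = "nlr_repertoire")
}

#' @export
print.nlr_repertoire <- function(x, ...) {
  cat("<nlr_repertoire> total ", x$total,
      if (!is.na(x$total_full)) paste0(" (full-length ", x$total_full, ", ",
                                       x$percent_full, "%)"), "\n", sep = "")
  if (!is.na(x$accession_mean)) {
    cat("  per accession: mean ", x$accession_mean, ", min ", x$accession_min,
        ", max ", x$accession_max, "\n", sep = "")
  }
  if (nrow(x$class_counts)) print(x$class_counts)
  invisible(x)
}

#' @rdname summarize_repertoire
#' @param x An `nlr_repertoire` object.
#' @param ... Unused.
#' @export
tidy.nlr_repertoire <- function(x, ...) x$class_counts

#' @rdname summarize_repertoire
#' @export
glance.nlr_repertoire <- function(x, ...) {
  tibble::tibble(total = x$total, total_full = x$total_full,
                 total_partial = x$total_partial,
                 accession_mean = x$accession_mean,
                 accession_min = x$accession_min,
                 accession_max = x$accession_max,
                 percent_full = x$percent_full,
                 percent_short_transcripts = x$percent_short_transcripts)
}

#' @rdname summarize_repertoire
#' @param object An `nlr_repertoire` object.
#' @export
autoplot.nlr_repertoire <- function(object, ...) {
  df <- object$class_counts
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$class_label, -.data$n),
                                   y = .data$n, fill = .data$is_full_length)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "architecture class", y = "genes",
                  fill = "full-length") +
    ggplot2::theme_minimal()
}
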