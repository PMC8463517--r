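# Relative expression from qPCR Ct tables (2^-dCt against an endogenous
# calibrator, e.g. the ubiquitin fusion protein gene).

#' Relative expression by the 2^-dCt method
#'
#' For each measurement, dCt = Ct(target) - Ct(reference) and relative
#' expression is `2^-dCt`; replicate groups are aggregated as mean and
#' standard error of the per-replicate expression values (not of dCt),
#' matching how such validations are plotted.
#'
#' @param ct Tibble with columns `sample_id`, `target_gene`, `ct_target`,
#'   `ct_reference` and optionally `replicate`; Ct values must lie in
#'   (0, 45) and the reference Ct must be present.
#' @param aggregate Average `"expression"` values (default) or `"dct"`
#'   before exponentiation.
#' @return Tibble with one row per (sample, gene): `n_replicates`,
#'   `mean_expression`, `se_expression`; per-replicate values are kept in
#'   `attr(, "replicates")`.
#' @export
#' @examples
#' ct <- tibble::tibble(sample_id = "s1", target_gene = "NLR1",
#'                      ct_target = c(26, 26.2, 25.8), ct_reference = 25,
#'                      replicate = 1:3)
#' relative_expression(ct)
relative_expression <- function(ct, aggregate = c("expression", "dct")) {
  aggregate <- match.arg(aggregate)
  need <- c("sample_id", "target_gene", "ct_target", "ct_reference")
  stopifnot(all(need %in% names(ct)))
  if (anyNA(ct$ct_reference)) stop("missing reference Ct")
  if (anyNA(ct$ct_target)) stop("missing target Ct")
  bad <- ct$ct_target <= 0 | ct$ct_target >= 45 |
    ct$ct_reference <= 0 | ct$ct_reference >= 45
  if (any(bad)) stop("Ct values must lie in (0, 45)")
  reps <- ct %>%
    dplyr::mutate(dct = .data$ct_target - .data$ct_reference,
                  expression = 2^(-.data$dct))
  out <- reps %>%
    dplyr::group_by(.data$sample_id, .data$target_gene) %>%
    dplyr::summarise(
      n_replicates = dplyr::n(),
      mean_expression = if (aggregate == "expression") mean(.data$expression)
                        else 2^(-mean(.data$dct)),
      se_expression = if (dplyr::n() > 1)
        stats::sd(.data$expression) / sqrt(dplyr::n()) else 0,
      .groups = "drop")
  attr(out, "replicates") <- reps
  out
}
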