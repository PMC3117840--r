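#' Select the top hit per spectrum
#'
#' Keeps, for every spectrum, the PSM with the lowest E-value.  Exact ties
#' are broken deterministically: lexicographically smallest peptide, then
#' smallest first mapped protein identifier.
#'
#' @param psms PSM tibble (schema of [read_psm_table()]).
#' @return Tibble with exactly one row per `spectrum_id`.
#' @export
select_top_hits <- function(psms) {
  if (nrow(psms) == 0L) return(psms)
  first_protein <- vapply(psms$protein_ids, `[[`, character(1), 1L)
  ord <- order(psms$spectrum_id, psms$e_value, psms$peptide, first_protein)
  out <- psms[ord, ]
  out[!duplicated(out$spectrum_id), ]
}

#' Decoy-based FDR estimate at an E-value threshold
#'
#' Accepts top hits with `e_value <= e_threshold` and estimates the false
#' discovery rate as the number of accepted decoy matches divided by the
#' number of all accepted positives (targets + decoys) — the convention in
#' which each reverse-database hit counts as one false positive among the
#' accepted identifications.  The `denominator = "targets"` alternative
#' divides by accepted target hits only.
#'
#' @param top_hits Output of [select_top_hits()].
#' @param e_threshold Positive E-value cutoff.
#' @param denominator `"all"` (accepted targets + decoys, default) or
#'   `"targets"`.
#' @return A one-row tibble: `e_threshold`, `n_accepted`,
#'   `n_decoy_accepted`, `fdr` (0 when nothing is accepted).
#' @export
estimate_fdr <- function(top_hits, e_threshold,
                         denominator = c("all", "targets")) {
  denominator <- match.arg(denominator)
  if (e_threshold < 0) stop("e_threshold must be non-negative")
  acc <- top_hits$e_value <= e_threshold
  n_acc <- sum(acc)
  n_dec <- sum(acc & top_hits$is_decoy)
  denom <- if (denominator == "all") n_acc else n_acc - n_dec
  tibble::tibble(
    e_threshold = e_threshold,
    n_accepted = n_acc,
    n_decoy_accepted = n_dec,
    fdr = if (denom > 0) n_dec / denom else 0
  )
}

#' Iterative E-value threshold selection from the decoy FDR
#'
#' Scans a descending grid of candidate thresholds (by default the sorted
#' distinct observed E-values) and returns the largest threshold whose
#' decoy-estimated FDR does not exceed `fdr_target`.  If no candidate
#' qualifies, an accept-nothing sentinel (half the smallest observed
#' E-value) is returned with a warning.
#'
#' @param top_hits Output of [select_top_hits()].
#' @param fdr_target Target FDR in (0, 1).
#' @param candidate_grid Optional descending vector of thresholds.
#' @param denominator Passed to [estimate_fdr()].
#' @return One-row FDR-estimate tibble for the selected threshold.
#' @export
select_e_threshold <- function(top_hits, fdr_target = 0.05,
                               candidate_grid = NULL,
                               denominator = c("all", "targets")) {
  denominator <- match.arg(denominator)
  if (nrow(top_hits) == 0L) stop("no PSMs to threshold")
  stopifnot(fdr_target > 0, fdr_target < 1)
  if (is.null(candidate_grid)) {
    # default grid = distinct observed e_values; one cumulative pass over
    # the sorted PSMs evaluates the whole descending scan at once
    ord <- order(top_hits$e_value)
    e <- top_hits$e_value[ord]
    n_acc <- seq_along(e)
    n_dec <- cumsum(top_hits$is_decoy[ord])
    last <- !duplicated(e, fromLast = TRUE)
    thr <- e[last]
    na <- n_acc[last]
    nd <- n_dec[last]
    denom <- if (denominator == "all") na else na - nd
    fdr <- ifelse(denom > 0, nd / denom, 0)
    ok <- which(fdr <= fdr_target)
    if (length(ok) > 0L) {
      i <- max(ok)
      return(tibble::tibble(e_threshold = thr[i], n_accepted = na[i],
                            n_decoy_accepted = nd[i], fdr = fdr[i]))
    }
  } else {
    for (thr in sort(candidate_grid, decreasing = TRUE)) {
      est <- estimate_fdr(top_hits, thr, denominator)
      if (est$fdr <= fdr_target) return(est)
    }
  }
  warning("no threshold meets the FDR target; accepting nothing")
  estimate_fdr(top_hits, min(top_hits$e_value) / 2, denominator)
}

#' Count unique peptides per protein, condition and replicate
#'
#' A peptide counts as unique when, across the accepted hits, it maps to
#' exactly one non-decoy protein; peptides shared between two or more
#' target proteins are excluded entirely, as are decoy matches.  Each
#' distinct peptide sequence contributes at most 1 to a protein's count in
#' a (condition, replicate), regardless of how many spectra matched it.
#'
#' @param accepted_top_hits Accepted (thresholded) top hits.
#' @param proteins Protein database tibble (to identify decoys).
#' @return Tibble `protein_id`, `condition`, `replicate`,
#'   `unique_peptides`.
#' @export
count_unique_peptides <- function(accepted_top_hits, proteins) {
  decoy_ids <- proteins$protein_id[proteins$is_decoy]
  hits <- accepted_top_hits[!accepted_top_hits$is_decoy, ]
  if (nrow(hits) == 0L) {
    return(tibble::tibble(protein_id = character(), condition = character(),
                          replicate = character(),
                          unique_peptides = integer()))
  }
  long <- tidyr::unnest(
    tibble::tibble(peptide = hits$peptide, protein_id = hits$protein_ids,
                   condition = hits$condition, replicate = hits$replicate),
    "protein_id"
  )
  long <- long[!long$protein_id %in% decoy_ids, ]
  # peptide -> number of distinct target proteins it maps to, dataset-wide
  pep_map <- dplyr::summarise(
    dplyr::group_by(long, .data$peptide),
    n_proteins = dplyr::n_distinct(.data$protein_id), .groups = "drop"
  )
  unique_peps <- pep_map$peptide[pep_map$n_proteins == 1L]
  long <- long[long$peptide %in% unique_peps, ]
  dplyr::summarise(
    dplyr::group_by(long, .data$protein_id, .data$condition, .data$replicate),
    unique_peptides = dplyr::n_distinct(.data$peptide), .groups = "drop"
  )
}

#' Presence calls from the two-replicate unique-peptide rule
#'
#' A protein is called present in a condition when at least 2 unique
#' peptides were identified in one biological replicate and at least 1 in
#' the other; the rule is symmetric in the two replicates.
#'
#' @param unique_peptide_counts Tibble `protein_id`, `condition`,
#'   `replicate`, `unique_peptides`; each condition must have exactly two
#'   replicate levels (absent rows count as zero).
#' @param replicates Optional character vector naming the two replicate
#'   levels; inferred from the data when `NULL`.
#' @return Tibble `protein_id`, `condition`, `unique_peptides_rep1`,
#'   `unique_peptides_rep2`, `present`.
#' @export
call_presence <- function(unique_peptide_counts, replicates = NULL) {
  upc <- unique_peptide_counts
  if (is.null(replicates)) replicates <- sort(unique(upc$replicate))
  if (length(replicates) != 2L) {
    stop("presence rule needs exactly two replicates, got ",
         length(replicates))
  }
  bad <- setdiff(unique(upc$replicate), replicates)
  if (length(bad) > 0L) stop("unknown replicate level: ", bad[[1]])
  wide <- tidyr::pivot_wider(
    upc,
    id_cols = c("protein_id", "condition"),
    names_from = "replicate", values_from = "unique_peptides",
    values_fill = 0L
  )
  for (r in replicates) if (!r %in% names(wide)) wide[[r]] <- 0L
  r1 <- wide[[replicates[1]]]
  r2 <- wide[[replicates[2]]]
  tibble::tibble(
    protein_id = wide$protein_id,
    condition = wide$condition,
    unique_peptides_rep1 = r1,
    unique_peptides_rep2 = r2,
    present = (r1 >= 2L & r2 >= 1L) | (r1 >= 1L & r2 >= 2L)
  )
}
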