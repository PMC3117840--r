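#' Pool spectral counts over replicates
#'
#' Sums per-replicate spectral counts within each condition; one NSAF and
#' one G statistic are reported per condition, so replicates are pooled by
#' summation first.
#'
#' @param counts Counts tibble (`protein_id`, `condition`, `replicate`,
#'   `spc`).
#' @return Tibble `protein_id`, `condition`, `spc`.
#' @export
pool_replicates <- function(counts) {
  dplyr::summarise(
    dplyr::group_by(counts, .data$protein_id, .data$condition),
    spc = sum(.data$spc), .groups = "drop"
  )
}

#' Normalized spectral abundance factor (NSAF) with pseudocounts
#'
#' For protein k in a condition,
#' \deqn{NSAF_k = \frac{(SpC_k + c) / L_k}{\sum_i (SpC_i + c) / L_i}}
#' where SpC is the pooled spectral count, L the protein length in
#' residues, c the pseudocount (default 0.5) and the sum runs over the
#' normalization universe.  The pseudocount is added uniformly to every
#' universe protein in every condition so that undetected proteins carry a
#' small positive abundance and cross-condition statistics stay defined;
#' per-condition NSAF values sum to exactly 1.
#'
#' @param pooled_counts Tibble from [pool_replicates()]; absent
#'   (protein, condition) pairs count as zero.
#' @param lengths Named vector or tibble (`protein_id`, `length`) of
#'   protein lengths.
#' @param pseudocount Non-negative pseudocount c.
#' @param universe Protein identifiers to normalize over — all proteins
#'   called present in any condition of the dataset.  Defaults to the
#'   proteins appearing in `pooled_counts`.
#' @param conditions Conditions to compute; defaults to those present.
#' @return Tibble `protein_id`, `condition`, `spc`, `nsaf`.
#' @export
compute_nsaf <- function(pooled_counts, lengths, pseudocount = 0.5,
                         universe = NULL, conditions = NULL) {
  stopifnot(pseudocount >= 0)
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths$length, lengths$protein_id)
  }
  if (is.null(universe)) universe <- sort(unique(pooled_counts$protein_id))
  if (length(universe) == 0L) stop("empty normalization universe")
  missing_len <- setdiff(universe, names(lengths))
  if (length(missing_len) > 0L) {
    stop("missing length for: ", paste(utils::head(missing_len), collapse = ", "))
  }
  if (is.null(conditions)) conditions <- sort(unique(pooled_counts$condition))
  grid <- tidyr::expand_grid(protein_id = universe, condition = conditions)
  grid <- dplyr::left_join(grid, pooled_counts,
                           by = c("protein_id", "condition"))
  grid$spc[is.na(grid$spc)] <- 0L
  grid$saf <- (grid$spc + pseudocount) / unname(lengths[grid$protein_id])
  out <- dplyr::mutate(
    dplyr::group_by(grid, .data$condition),
    nsaf = .data$saf / sum(.data$saf)
  )
  out <- dplyr::ungroup(out)
  out$saf <- NULL
  out
}
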