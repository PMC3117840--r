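#' Read a protein database from FASTA
#'
#' Parses a FASTA file of amino-acid sequences into a protein table.  The
#' protein identifier is the first whitespace-delimited token of the header;
#' entries whose identifier starts with `decoy_prefix` are flagged as decoys
#' (reverse-database entries used for FDR estimation).
#'
#' @param path Path to a FASTA file.
#' @param decoy_prefix Header prefix marking reverse-decoy entries.
#' @param keep_sequence Keep the sequence column (needed only when writing
#'   the database back out).
#' @return A tibble with columns `protein_id`, `length` (residues),
#'   `is_decoy`, and optionally `sequence`.
#' @export
read_fasta <- function(path, decoy_prefix = "rev_", keep_sequence = FALSE) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first[[1]], ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- Biostrings::width(seqs)
  if (any(lens == 0L)) {
    stop("empty sequence for: ", paste(ids[lens == 0L], collapse = ", "))
  }
  out <- tibble::tibble(
    protein_id = ids,
    length = as.integer(lens),
    is_decoy = startsWith(ids, decoy_prefix)
  )
  if (keep_sequence) out$sequence <- unname(as.character(seqs))
  out
}

#' Write a protein database to FASTA
#'
#' @param proteins Tibble with `protein_id` and `sequence` columns.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- proteins$protein_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.psm_columns <- c("spectrum_id", "peptide", "protein_ids", "e_value",
                  "condition", "replicate")

#' Read a PSM table
#'
#' Reads a headered, tab-separated peptide-spectrum-match table.  Required
#' columns: `spectrum_id`, `peptide`, `protein_ids` (semicolon-delimited
#' list of protein identifiers), `e_value`, `condition`, `replicate`.  The
#' decoy flag of each PSM is derived from the protein database: a PSM is a
#' decoy match iff every protein it maps to is a decoy.
#'
#' @param path Path to the TSV file.
#' @param proteins Protein table from [read_fasta()]; used to validate
#'   identifiers and derive `is_decoy`.  `NULL` skips validation and sets
#'   `is_decoy` from a `decoy_prefix` match instead.
#' @param decoy_prefix Fallback decoy prefix when `proteins` is `NULL`.
#' @return Tibble of PSMs with a list-column `protein_ids` and a logical
#'   `is_decoy`.
#' @export
read_psm_table <- function(path, proteins = NULL, decoy_prefix = "rev_") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(.psm_columns, names(raw))
  if (length(missing_cols) > 0L) {
    stop("PSM table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  e_value <- suppressWarnings(as.numeric(raw$e_value))
  bad <- which(!is.finite(e_value))
  if (length(bad) > 0L) {
    stop("non-numeric e_value at row ", bad[[1]])
  }
  bad <- which(e_value <= 0)
  if (length(bad) > 0L) {
    stop("e_value must be > 0; violated at row ", bad[[1]])
  }
  ids <- strsplit(raw$protein_ids, ";", fixed = TRUE)
  if (any(lengths(ids) == 0L)) {
    stop("empty protein_ids at row ", which(lengths(ids) == 0L)[[1]])
  }
  if (!is.null(proteins)) {
    known <- proteins$protein_id
    unknown <- vapply(ids, function(x) any(!x %in% known), logical(1))
    if (any(unknown)) {
      i <- which(unknown)[[1]]
      stop("unknown protein_id '",
           setdiff(ids[[i]], known)[[1]], "' at row ", i)
    }
    decoy_ids <- proteins$protein_id[proteins$is_decoy]
    is_decoy <- vapply(ids, function(x) all(x %in% decoy_ids), logical(1))
  } else {
    is_decoy <- vapply(ids, function(x) all(startsWith(x, decoy_prefix)),
                       logical(1))
  }
  tibble::tibble(
    spectrum_id = raw$spectrum_id,
    peptide = raw$peptide,
    protein_ids = ids,
    e_value = e_value,
    condition = raw$condition,
    replicate = raw$replicate,
    is_decoy = is_decoy
  )
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: the `protein_ids` list-column is collapsed
#' with semicolons; the derived `is_decoy` column is not written.
#'
#' @param psms PSM tibble.
#' @param path Output path.
#' @export
write_psm_table <- function(psms, path) {
  out <- tibble::tibble(
    spectrum_id = psms$spectrum_id,
    peptide = psms$peptide,
    protein_ids = vapply(psms$protein_ids, paste, character(1),
                         collapse = ";"),
    e_value = psms$e_value,
    condition = psms$condition,
    replicate = psms$replicate
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a spectral-count table
#'
#' Long-format TSV with columns `protein_id`, `condition`, `replicate`,
#' `spc` (spectral counts) and `unique_peptides`.
#'
#' @param path Path to the TSV file.
#' @return Tibble of per-replicate counts.
#' @export
read_counts_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = "c", condition = "c", replicate = "c",
    spc = "i", unique_peptides = "i"
  ), progress = FALSE)
  if (any(x$spc < 0) || any(x$unique_peptides < 0)) {
    stop("negative counts in ", path)
  }
  x
}

#' Read a protein annotation table
#'
#' TSV with columns `protein_id`, `signal_peptide` (TRUE/FALSE),
#' `enzyme_class`, `functional_category`.  Missing optional columns are
#' tolerated.
#'
#' @param path Path to the TSV file.
#' @return Tibble of annotations.
#' @export
read_annotation_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!"protein_id" %in% names(x)) stop("annotation table needs protein_id")
  if ("signal_peptide" %in% names(x)) {
    x$signal_peptide <- as.logical(x$signal_peptide)
  }
  x
}

#' Read a qPCR Ct table
#'
#' Comma-separated, headered table with columns `gene`, `condition`,
#' `replicate`, `ct_target`, `ct_spike` and optionally `eff_target`,
#' `eff_spike` (amplification efficiencies as fold per cycle, in (1, 2];
#' default 2 when absent).
#'
#' @param path Path to the CSV file.
#' @return Tibble of Ct records.
#' @export
read_ct_table <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    gene = "c", condition = "c", replicate = "c", .default = "d"
  ), progress = FALSE)
  need <- c("gene", "condition", "replicate", "ct_target", "ct_spike")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stop("Ct table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"eff_target" %in% names(x)) x$eff_target <- 2
  if (!"eff_spike" %in% names(x)) x$eff_spike <- 2
  if (any(!is.finite(x$ct_target)) || any(!is.finite(x$ct_spike))) {
    stop("non-finite Ct value in ", path)
  }
  if (any(x$eff_target <= 1 | x$eff_target > 2) ||
      any(x$eff_spike <= 1 | x$eff_spike > 2)) {
    stop("efficiencies must lie in (1, 2]")
  }
  x
}

#' Write a results table
#'
#' Tab-separated, UTF-8, '.' decimal separator, fixed column order as given.
#' Numeric (double) columns are rounded to `digits` significant digits.
#'
#' @param records Data frame of results.
#' @param path Output path.
#' @param digits Significant digits for floating-point columns.
#' @export
write_results_table <- function(records, path, digits = 4) {
  out <- as.data.frame(records)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      x <- signif(out[[nm]], digits)
      # fixed (non-scientific) notation with trailing zeros dropped
      out[[nm]] <- vapply(x, function(v) {
        if (is.na(v)) NA_character_
        else format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
      }, character(1))
    }
  }
  readr::write_tsv(out, path, progress = FALSE, escape = "none")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to the TSV file.
#' @return Tibble with types guessed per column.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                  show_col_types = FALSE)
}
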