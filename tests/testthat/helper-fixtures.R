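# Small in-code fixtures shared across test files.

make_psms <- function(spectrum_id, peptide, protein_ids, e_value,
                      condition = "d-maltose", replicate = "rep1",
                      is_decoy = NULL) {
  if (is.null(is_decoy)) {
    is_decoy <- vapply(protein_ids, function(x) all(startsWith(x, "rev_")),
                       logical(1))
  }
  tibble::tibble(
    spectrum_id = spectrum_id, peptide = peptide,
    protein_ids = protein_ids, e_value = e_value,
    condition = condition, replicate = replicate, is_decoy = is_decoy
  )
}

write_tmp_fasta <- function(entries, path = withr::local_tempfile(
                              fileext = ".fasta", .local_envir = parent.frame())) {
  writeLines(unlist(lapply(names(entries), function(id) {
    c(paste0(">", id), entries[[id]])
  })), path)
  path
}

# brute-force Venn regions by direct set enumeration
brute_venn <- function(presence_calls) {
  conds <- unique(presence_calls$condition)
  present <- presence_calls[presence_calls$present, ]
  ids <- unique(present$protein_id)
  regions <- vapply(ids, function(p) {
    s <- present$condition[present$protein_id == p]
    paste(conds[conds %in% s], collapse = "&")
  }, character(1))
  list(region_counts = table(regions), total = length(ids))
}
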