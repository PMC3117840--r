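#!/usr/bin/env Rscript
# Identification stage: top-hit selection per spectrum, E-value threshold
# from the decoy FDR at a 5% target, and unique-peptide presence calls
# under the 2+1 replicate rule.  Reads results/sim/, writes
# results/identification/<fraction>/.

suppressMessages(library(secspec))

for (fraction in c("secretome", "microsome")) {
  indir <- file.path("results/sim", fraction)
  outdir <- file.path("results/identification", fraction)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  proteins <- read_fasta(file.path(indir, "proteome.fasta"))
  psms <- read_psm_table(file.path(indir, "psms.tsv"), proteins)
  top <- select_top_hits(psms)
  sel <- select_e_threshold(top, fdr_target = 0.05)
  write_results_table(sel, file.path(outdir, "fdr.tsv"), digits = 6)
  message(sprintf(
    "[%s] E-value threshold %.3g accepts %d PSMs (%d decoys, FDR %.2f%%)",
    fraction, sel$e_threshold, sel$n_accepted, sel$n_decoy_accepted,
    100 * sel$fdr))

  # presence from the per-replicate unique-peptide counts of the count table
  counts <- read_counts_table(file.path(indir, "counts.tsv"))
  presence <- call_presence(
    counts[, c("protein_id", "condition", "replicate", "unique_peptides")]
  )
  write_results_table(presence, file.path(outdir, "presence.tsv"))
  per_cond <- table(presence$condition[presence$present])
  message(sprintf("[%s] proteins present per condition: %s", fraction,
                  paste(names(per_cond), per_cond, sep = "=",
                        collapse = ", ")))
}
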