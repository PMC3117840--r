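#!/usr/bin/env Rscript
# Quantification stage: pool replicates and compute pseudocounted NSAF over
# the union of proteins present in any condition of each fraction.  Writes
# results/quant/<fraction>/nsaf.tsv.

suppressMessages(library(secspec))

for (fraction in c("secretome", "microsome")) {
  proteins <- read_fasta(file.path("results/sim", fraction, "proteome.fasta"))
  counts <- read_counts_table(file.path("results/sim", fraction, "counts.tsv"))
  presence <- read_results_table(
    file.path("results/identification", fraction, "presence.tsv"))
  universe <- sort(unique(presence$protein_id[presence$present]))

  nsaf <- compute_nsaf(pool_replicates(counts), proteins,
                       pseudocount = 0.5, universe = universe)
  outdir <- file.path("results/quant", fraction)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(nsaf, file.path(outdir, "nsaf.tsv"), digits = 6)

  top <- nsaf[nsaf$condition == "d-maltose", ]
  top <- top[order(-top$nsaf), ][1:3, ]
  message(sprintf(
    "[%s] NSAF universe %d proteins; most abundant on d-maltose: %s",
    fraction, length(universe),
    paste(sprintf("%s (%.3g)", top$protein_id, top$nsaf), collapse = ", ")))
}
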