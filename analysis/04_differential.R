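#!/usr/bin/env Rscript
# Differential stage: per-protein G-tests of each induction condition
# against the d-sorbitol control on pooled pseudocounted counts, and the
# selection summaries (G > 10 discussion set, top 25% increased / top 10%
# decreased).  Compares calls against the simulation truth.

suppressMessages(library(secspec))

for (fraction in c("secretome", "microsome")) {
  counts <- read_counts_table(file.path("results/sim", fraction, "counts.tsv"))
  nsaf <- read_results_table(file.path("results/quant", fraction, "nsaf.tsv"))
  universe <- sort(unique(nsaf$protein_id))
  pooled <- pool_replicates(counts)

  res <- test_all_proteins(pooled, nsaf, control = "d-sorbitol",
                           pseudocount = 0.5, universe = universe)
  outdir <- file.path("results/difftest", fraction)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(res, file.path(outdir, "gtest.tsv"), digits = 6)

  truth <- readr::read_tsv(file.path("results/sim", fraction, "truth.tsv"),
                           show_col_types = FALSE)
  for (ct in unique(res$contrast)) {
    sub <- res[res$contrast == ct, ]
    sel <- summarize_selection(sub)
    cond <- sub("(.*) vs .*", "\\1", ct)
    tru <- truth$protein_id[truth$condition == cond &
                              truth$protein_id %in% universe]
    called <- sub$protein_id[sub$significant_05]
    message(sprintf(
      "[%s] %s: %d significant (G>=3.841), %d discussed (G>10); recovered %d/%d simulated differential proteins",
      fraction, ct, sum(sub$significant_05), nrow(sel$discussed),
      sum(tru %in% called), length(tru)))
    safe <- gsub("[^A-Za-z0-9._-]+", "_", ct)
    write_results_table(sel$discussed,
                        file.path(outdir, paste0("discussed_", safe, ".tsv")),
                        digits = 6)
  }
}
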