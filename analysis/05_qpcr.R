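#!/usr/bin/env Rscript
# qPCR stage: Pfaffl relative expression double-normalized to the exogenous
# spike transcript and to the d-sorbitol control average; compares the
# recovered fold changes with the simulated truth.

suppressMessages(library(secspec))

ct <- read_ct_table("results/sim/secretome/ct.csv")
rel <- double_normalize(ct, "d-sorbitol")
summary <- summarize_expression(rel)

dir.create("results/qpcr", recursive = TRUE, showWarnings = FALSE)
write_results_table(rel, "results/qpcr/relative_expression.tsv", digits = 6)
write_results_table(summary, "results/qpcr/summary.tsv", digits = 6)

truth <- readr::read_tsv("results/sim/secretome/qpcr_truth.tsv",
                         show_col_types = FALSE)
cmp <- merge(summary, truth, by = c("gene", "condition"))
for (i in seq_len(nrow(cmp))) {
  message(sprintf("%s on %s: recovered ratio %.2f (true %.2f)",
                  cmp$gene[i], cmp$condition[i], cmp$ratio.x[i],
                  cmp$ratio.y[i]))
}
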