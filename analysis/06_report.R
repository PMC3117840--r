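#!/usr/bin/env Rscript
# Reporting stage: Venn region counts of presence across conditions,
# enzyme-class distributions of present proteins, and the table of proteins
# shared by the secretome and microsomal fractions with display-scaled
# NSAF values.

suppressMessages(library(secspec))

dir.create("results/reports", recursive = TRUE, showWarnings = FALSE)
nsafs <- list()
for (fraction in c("secretome", "microsome")) {
  presence <- read_results_table(
    file.path("results/identification", fraction, "presence.tsv"))
  v <- venn_counts(presence)
  venn_tbl <- tibble::tibble(region = names(v$region_counts),
                             n = v$region_counts)
  write_results_table(venn_tbl,
                      file.path("results/reports",
                                paste0("venn_", fraction, ".tsv")))
  message(sprintf("[%s] %d proteins present in >=1 condition; regions: %s",
                  fraction, v$total,
                  paste(venn_tbl$region, venn_tbl$n, sep = "=",
                        collapse = ", ")))

  ann <- read_annotation_table(
    file.path("results/sim", fraction, "annotations.tsv"))
  dist <- class_distribution(presence, ann)
  write_results_table(dist,
                      file.path("results/reports",
                                paste0("class_distribution_", fraction, ".tsv")))

  nsafs[[fraction]] <- read_results_table(
    file.path("results/quant", fraction, "nsaf.tsv"))
}

shared <- shared_protein_table(nsafs$secretome, nsafs$microsome,
                               control = "d-sorbitol")
write_results_table(shared, "results/reports/shared_proteins.tsv")
message(sprintf("%d (protein, condition) rows shared between fractions",
                nrow(shared)))
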