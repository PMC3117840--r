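#!/usr/bin/env Rscript
# Generate the ground-truthed synthetic study: two proteome fractions
# (secretome, microsome), each 200 proteins x 3 conditions (d-maltose,
# d-xylose, d-sorbitol control) x 2 biological replicates at 5000 spectra
# per replicate, plus a decoy-contaminated PSM list and a qPCR Ct table.
# Writes everything under results/sim/<fraction>/.

suppressMessages(library(secspec))

seed <- 101L

for (fraction in c("secretome", "microsome")) {
  fseed <- seed + match(fraction, c("secretome", "microsome")) * 1000L
  proteins <- generate_proteome(200, seed = fseed)
  truth <- generate_truth(proteins, seed = fseed + 1L)
  counts <- simulate_spectral_counts(truth)
  psms <- simulate_psms(n_true = 5000, n_false = 5000,
                        proteins = make_decoy_db(proteins),
                        seed = fseed + 2L)
  dir.create(file.path("results/sim", fraction), recursive = TRUE,
             showWarnings = FALSE)
  ct <- NULL
  if (fraction == "secretome") {
    # the genes profiled by qPCR: induced, repressed and unchanged cases
    qpcr_truth <- tibble::tibble(
      gene = rep(c("glaA", "aamA", "abnC"), each = 2),
      condition = rep(c("d-maltose", "d-xylose"), 3),
      ratio = c(8, 1, 4, 0.8, 2.5, 1.2)
    )
    ct <- simulate_qpcr(qpcr_truth, control = "d-sorbitol",
                        ct_noise_sd = 0.2, seed = fseed + 3L)
    readr::write_tsv(qpcr_truth,
                     file.path("results/sim", fraction, "qpcr_truth.tsv"))
  }
  paths <- write_simulation(truth, counts, psms, ct,
                            file.path("results/sim", fraction))

  # annotations: enzyme classes skewed towards hydrolases, as in a
  # carbohydrate-active secretome
  withr::with_seed(fseed + 4L, {
    ann <- tibble::tibble(
      protein_id = proteins$protein_id,
      signal_peptide = runif(200) < 0.6,
      enzyme_class = sample(
        c("hydrolase", "oxidoreductase", "transferase", "lyase",
          "isomerase", "ligase", "non-enzyme"),
        200, replace = TRUE,
        prob = c(0.45, 0.1, 0.08, 0.05, 0.03, 0.02, 0.27)
      )
    )
    readr::write_tsv(ann, file.path("results/sim", fraction, "annotations.tsv"))
  })
  message(sprintf(
    "[%s] %d proteins, %d differential (%d increased / %d decreased per contrast)",
    fraction, nrow(proteins), nrow(truth$differential),
    sum(truth$differential$direction == "increased") / 2,
    sum(truth$differential$direction == "decreased") / 2))
}
message("synthetic inputs written under results/sim/")
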