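Package: secspec
Title: Spectral-Count Proteomics of Induced Fungal Secretomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Label-free spectral-count analysis of secretome and microsomal
    proteomes across induction conditions: target-decoy filtering of
    peptide-spectrum matches with an iteratively selected E-value threshold,
    unique-peptide presence calling over biological replicates,
    pseudocounted NSAF (normalized spectral abundance factor)
    quantification, pairwise likelihood-ratio G-tests of each induction
    condition against a non-inducing control, selection and reporting
    summaries (Venn region counts, enzyme-class distributions, shared
    secretome/microsome tables), and Pfaffl efficiency-corrected qPCR
    ratios double-normalized to an exogenous spike transcript and the
    control condition.  A ground-truthed synthetic-data generator with a
    multinomial spectral-count model makes the whole pipeline testable
    without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
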