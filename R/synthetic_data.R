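#' @importFrom rlang .data
#' @importFrom stats rpois rnorm runif rmultinom setNames
NULL

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a synthetic protein universe
#'
#' Protein lengths are drawn log-normally (rounded up, floor of 50
#' residues), the typical shape of proteome length distributions.  Random
#' amino-acid sequences of the drawn lengths are attached so the universe
#' can be written to FASTA and round-tripped.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_log_mean,length_log_sd Parameters of the log-normal length
#'   distribution (natural log of residues).  Defaults centre the
#'   distribution near 400 residues.
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return Tibble with `protein_id`, `length`, `is_decoy` (all `FALSE`) and
#'   `sequence`.
#' @export
generate_proteome <- function(n_proteins, length_log_mean = log(400),
                              length_log_sd = 0.45, seed = 1L) {
  stopifnot(n_proteins >= 1, length_log_sd >= 0)
  .with_seed(seed, {
    lens <- pmax(50L, as.integer(ceiling(exp(
      rnorm(n_proteins, length_log_mean, length_log_sd)))))
    seqs <- vapply(lens, function(L) {
      paste(sample(.AA, L, replace = TRUE), collapse = "")
    }, character(1))
    tibble::tibble(
      protein_id = sprintf("P%04d", seq_len(n_proteins)),
      length = lens,
      is_decoy = FALSE,
      sequence = seqs
    )
  })
}

#' Reverse-decoy database
#'
#' Appends, for every target protein, an entry with the reversed sequence
#' and the decoy prefix on its identifier — the construction used for
#' target-decoy FDR estimation.
#'
#' @param proteins Target protein tibble with sequences.
#' @param prefix Decoy identifier prefix.
#' @return Tibble of targets followed by decoys.
#' @export
make_decoy_db <- function(proteins, prefix = "rev_") {
  rev_seq <- vapply(strsplit(proteins$sequence, ""), function(x) {
    paste(rev(x), collapse = "")
  }, character(1))
  decoys <- tibble::tibble(
    protein_id = paste0(prefix, proteins$protein_id),
    length = proteins$length,
    is_decoy = TRUE,
    sequence = rev_seq
  )
  dplyr::bind_rows(proteins, decoys)
}

#' Ground truth for a simulated spectral-count experiment
#'
#' Builds per-condition relative abundance vectors over the protein
#' universe.  The baseline (control) profile is uniform by default or
#' Dirichlet-distributed; in each induction condition the designated
#' differential proteins have their abundance multiplied by their fold
#' change and the vector is renormalized to sum to one.
#'
#' Relative abundances are a closed composition: a one-sided perturbation
#' plus renormalization would shift every non-differential protein and make
#' the nominal nulls genuinely differential.  The default design is
#' therefore two-sided and mass-balanced — per contrast, `n_increased`
#' proteins at `fold_increase` and `n_decreased` at `fold_decrease`, with
#' `n_increased * (fold_increase - 1) = n_decreased * (1 - fold_decrease)`
#' under the uniform baseline — so non-differential proteins keep exactly
#' their control abundance and behave as true nulls.
#'
#' @param proteins Protein tibble (targets only).
#' @param conditions Condition names; `control` must be among them.
#' @param control Name of the non-inducing control condition.
#' @param n_increased,n_decreased Differential proteins per induction
#'   condition in each direction (disjoint sets across conditions).
#' @param fold_increase,fold_decrease Abundance multipliers (positive,
#'   != 1) for the two directions.
#' @param depth Total spectral counts per (condition, replicate).
#' @param n_replicates Biological replicates per condition.
#' @param dirichlet_alpha `NULL` for a uniform baseline, or a positive
#'   concentration for a symmetric Dirichlet baseline.
#' @param seed Integer seed.
#' @return A list of class `simulation_truth`: `proteins`, `abundance`
#'   (condition x protein matrix, rows sum to 1), `differential` (tibble
#'   `protein_id`, `condition`, `fold_change`, `direction`), `depth`
#'   (tibble `condition`, `replicate`, `depth`), `conditions`, `control`,
#'   `seed`.
#' @export
generate_truth <- function(proteins,
                           conditions = c("d-maltose", "d-xylose", "d-sorbitol"),
                           control = "d-sorbitol",
                           n_increased = 2L,
                           n_decreased = 10L,
                           fold_increase = 5,
                           fold_decrease = 0.2,
                           depth = 5000L,
                           n_replicates = 2L,
                           dirichlet_alpha = NULL,
                           seed = 1L) {
  stopifnot(control %in% conditions,
            fold_increase > 0, fold_decrease > 0,
            n_increased >= 0, n_decreased >= 0)
  n <- nrow(proteins)
  test_conditions <- setdiff(conditions, control)
  n_per <- n_increased + n_decreased
  n_diff_total <- n_per * length(test_conditions)
  if (n_diff_total > n) stop("n_differential exceeds universe size")
  .with_seed(seed, {
    if (is.null(dirichlet_alpha)) {
      base <- rep(1 / n, n)
    } else {
      g <- stats::rgamma(n, shape = dirichlet_alpha)
      base <- g / sum(g)
    }
    abundance <- matrix(rep(base, each = length(conditions)),
                        nrow = length(conditions),
                        dimnames = list(conditions, proteins$protein_id),
                        byrow = FALSE)
    diff_ids <- if (n_diff_total > 0) {
      sample(proteins$protein_id, n_diff_total)
    } else character(0)
    differential <- tibble::tibble(
      protein_id = diff_ids,
      condition = rep(test_conditions, each = n_per),
      fold_change = rep(rep(c(fold_increase, fold_decrease),
                            c(n_increased, n_decreased)),
                        length(test_conditions)),
      direction = rep(rep(c("increased", "decreased"),
                          c(n_increased, n_decreased)),
                      length(test_conditions))
    )
    differential <- differential[differential$fold_change != 1, ]
    for (cond in test_conditions) {
      sel <- differential$condition == cond
      v <- abundance[cond, ]
      v[differential$protein_id[sel]] <-
        v[differential$protein_id[sel]] * differential$fold_change[sel]
      abundance[cond, ] <- v / sum(v)
    }
    depth_tbl <- tidyr::expand_grid(
      condition = conditions,
      replicate = paste0("rep", seq_len(n_replicates))
    )
    depth_tbl$depth <- as.integer(depth)
    structure(list(
      proteins = proteins,
      abundance = abundance,
      differential = differential,
      depth = depth_tbl,
      conditions = conditions,
      control = control,
      seed = seed
    ), class = "simulation_truth")
  })
}

#' Simulate spectral counts from a ground truth
#'
#' For each (condition, replicate), spectral counts are drawn multinomially
#' with total equal to the sequencing depth and per-protein probability
#' proportional to abundance x length: longer proteins yield proportionally
#' more tryptic peptides and hence more spectra, which is exactly the bias
#' NSAF divides back out.  Unique-peptide counts per protein and replicate
#' are a simple coupled draw, `min(ceiling(spc / 2), Poisson(1 + spc / 3))`,
#' whose only role is to exercise the presence filter at both margins.
#'
#' @param truth A `simulation_truth` from [generate_truth()].
#' @param seed Integer seed (defaults to `truth$seed + 1`).
#' @return Tibble with `protein_id`, `condition`, `replicate`, `spc`,
#'   `unique_peptides`.
#' @export
simulate_spectral_counts <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (is.null(seed)) seed <- truth$seed + 1L
  lens <- truth$proteins$length
  ids <- truth$proteins$protein_id
  .with_seed(seed, {
    rows <- purrr::pmap(truth$depth, function(condition, replicate, depth) {
      w <- truth$abundance[condition, ] * lens
      p <- w / sum(w)
      spc <- if (depth > 0) {
        as.integer(rmultinom(1, size = depth, prob = p))
      } else {
        integer(length(p))
      }
      upc <- pmin(as.integer(ceiling(spc / 2)), rpois(length(spc), 1 + spc / 3))
      tibble::tibble(protein_id = ids, condition = condition,
                     replicate = replicate, spc = spc,
                     unique_peptides = as.integer(upc))
    })
    dplyr::bind_rows(rows)
  })
}

.rand_peptides <- function(n, min_len = 8L, max_len = 15L) {
  if (n == 0L) return(character(0))
  lens <- sample(seq(min_len, max_len), n, replace = TRUE)
  chars <- matrix(sample(.AA, n * max_len, replace = TRUE), nrow = n)
  full <- do.call(paste0, as.data.frame(chars))
  substring(full, 1L, lens)
}

#' Simulate a decoy-contaminated PSM list
#'
#' Produces one top-hit PSM per spectrum from a two-component E-value
#' mixture: true matches with small E-values (log-uniform on
#' `e_true_range`) mapped to target proteins, and false matches with large
#' E-values (log-uniform on `e_false_range`) mapped to a reverse-decoy
#' protein with probability `decoy_fraction_of_false` and to a random
#' target otherwise.  The hidden label is kept in the `true_hit` column for
#' evaluating the decoy FDR estimator; pipeline code never reads it.
#'
#' @param n_true,n_false Numbers of true and false PSMs.
#' @param e_true_range,e_false_range Log-uniform E-value supports.
#' @param decoy_fraction_of_false Probability that a false PSM maps to a
#'   decoy protein.
#' @param proteins Optional protein database (targets + decoys); a small
#'   internal universe is generated when `NULL`.
#' @param condition,replicate Labels stamped on every PSM.
#' @param seed Integer seed.
#' @return Tibble of PSM records (same schema as [read_psm_table()]) plus
#'   the hidden `true_hit` logical.
#' @export
simulate_psms <- function(n_true = 5000L, n_false = 5000L,
                          e_true_range = c(1e-8, 1e-3),
                          e_false_range = c(1e-3, 10),
                          decoy_fraction_of_false = 0.5,
                          proteins = NULL,
                          condition = "d-maltose", replicate = "rep1",
                          seed = 1L) {
  stopifnot(n_true >= 0, n_false >= 0,
            all(e_true_range > 0), all(e_false_range > 0),
            decoy_fraction_of_false >= 0, decoy_fraction_of_false <= 1)
  .with_seed(seed, {
    if (is.null(proteins)) {
      targets <- sprintf("P%04d", seq_len(100))
      decoys <- paste0("rev_", targets)
    } else {
      targets <- proteins$protein_id[!proteins$is_decoy]
      decoys <- proteins$protein_id[proteins$is_decoy]
      if (length(decoys) == 0L) stop("protein database has no decoys")
    }
    n <- n_true + n_false
    true_hit <- c(rep(TRUE, n_true), rep(FALSE, n_false))
    loguni <- function(m, range) exp(runif(m, log(range[1]), log(range[2])))
    e_value <- c(loguni(n_true, e_true_range), loguni(n_false, e_false_range))
    to_decoy <- c(rep(FALSE, n_true),
                  runif(n_false) < decoy_fraction_of_false)
    protein_id <- character(n)
    protein_id[!to_decoy] <- sample(targets, sum(!to_decoy), replace = TRUE)
    protein_id[to_decoy] <- sample(decoys, sum(to_decoy), replace = TRUE)
    ord <- sample.int(n)
    tibble::tibble(
      spectrum_id = sprintf("spec%06d", seq_len(n)),
      peptide = .rand_peptides(n),
      protein_ids = as.list(protein_id[ord]),
      e_value = e_value[ord],
      condition = condition,
      replicate = replicate,
      is_decoy = to_decoy[ord],
      true_hit = true_hit[ord]
    )
  })
}

#' Simulate a qPCR Ct table with known true expression ratios
#'
#' Ct values are constructed so that the noiseless Pfaffl double-normalized
#' ratio (see [double_normalize()]) equals the requested true ratio: the
#' spike Ct is constant and the target Ct of a sample with ratio r sits
#' `log(r) / log(eff_target)` cycles below the control target Ct.  Gaussian
#' cycle noise of sd `ct_noise_sd` is then added independently to every
#' target and spike Ct.
#'
#' @param true_ratios Tibble `gene`, `condition`, `ratio` (positive; the
#'   control condition is implicitly 1 and need not be listed).
#' @param control Control condition name.
#' @param eff_target,eff_spike Amplification efficiencies in (1, 2].
#' @param ct_noise_sd Gaussian sd of cycle noise (0 for noiseless).
#' @param n_replicates Biological replicates per condition.
#' @param ct_target_base,ct_spike_base Baseline cycles for the control.
#' @param seed Integer seed.
#' @return Tibble of Ct records (schema of [read_ct_table()]).
#' @export
simulate_qpcr <- function(true_ratios, control = "d-sorbitol",
                          eff_target = 2, eff_spike = 2,
                          ct_noise_sd = 0, n_replicates = 2L,
                          ct_target_base = 25, ct_spike_base = 20,
                          seed = 1L) {
  stopifnot(all(true_ratios$ratio > 0), ct_noise_sd >= 0)
  if (any(eff_target <= 1 | eff_target > 2) ||
      any(eff_spike <= 1 | eff_spike > 2)) {
    stop("efficiencies must lie in (1, 2]")
  }
  conditions <- union(control, unique(true_ratios$condition))
  genes <- unique(true_ratios$gene)
  grid <- tidyr::expand_grid(
    gene = genes, condition = conditions,
    replicate = paste0("rep", seq_len(n_replicates))
  )
  grid <- dplyr::left_join(grid, true_ratios, by = c("gene", "condition"))
  grid$ratio[grid$condition == control] <- 1
  if (any(is.na(grid$ratio))) {
    stop("true_ratios missing for some (gene, condition)")
  }
  .with_seed(seed, {
    grid$ct_target <- ct_target_base - log(grid$ratio) / log(eff_target) +
      rnorm(nrow(grid), 0, ct_noise_sd)
    grid$ct_spike <- ct_spike_base + rnorm(nrow(grid), 0, ct_noise_sd)
    grid$eff_target <- eff_target
    grid$eff_spike <- eff_spike
    grid[, c("gene", "condition", "replicate", "ct_target", "ct_spike",
             "eff_target", "eff_spike")]
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Writes the FASTA database (targets + decoys), the spectral-count TSV,
#' the PSM TSV, the Ct CSV and a truth TSV (differential proteins) under
#' `dir`, so the full pipeline can be run from files alone.
#'
#' @param truth `simulation_truth` object.
#' @param counts Counts tibble from [simulate_spectral_counts()].
#' @param psms PSM tibble from [simulate_psms()].
#' @param ct Ct tibble from [simulate_qpcr()], or `NULL`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_simulation <- function(truth, counts, psms, ct = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- make_decoy_db(truth$proteins)
  paths <- list(
    fasta = file.path(dir, "proteome.fasta"),
    counts = file.path(dir, "counts.tsv"),
    psms = file.path(dir, "psms.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(db, paths$fasta)
  readr::write_tsv(counts, paths$counts, progress = FALSE)
  write_psm_table(psms, paths$psms)
  readr::write_tsv(truth$differential, paths$truth, progress = FALSE)
  if (!is.null(ct)) {
    paths$ct <- file.path(dir, "ct.csv")
    readr::write_csv(ct, paths$ct, progress = FALSE)
  }
  invisible(paths)
}
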