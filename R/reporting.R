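#' Venn region counts of protein presence across conditions
#'
#' Partitions the proteins present in at least one condition into exclusive
#' Venn regions.  Region names join the member conditions with `&` in the
#' input condition order.
#'
#' @param presence_calls Presence tibble from [call_presence()] (2 or 3
#'   conditions).
#' @return List with `region_counts` (named integer vector over non-empty
#'   regions observed) and `total` (number of distinct proteins present
#'   anywhere).
#' @export
venn_counts <- function(presence_calls) {
  conds <- unique(presence_calls$condition)
  if (length(conds) < 2L || length(conds) > 3L) {
    stop("venn_counts supports 2-3 conditions; use a presence matrix instead")
  }
  present <- presence_calls[presence_calls$present, ]
  sets <- split(present$condition, present$protein_id)
  region_of <- vapply(sets, function(s) {
    paste(conds[conds %in% s], collapse = "&")
  }, character(1))
  counts <- table(region_of)
  list(
    region_counts = setNames(as.integer(counts), names(counts)),
    total = length(sets)
  )
}

#' Enzyme-class distribution of present proteins per condition
#'
#' Percentage of present proteins in each annotation class, per condition;
#' proteins missing from the annotation table fall into class `"unknown"`.
#' Percentages within a condition sum to 100.
#'
#' @param presence_calls Presence tibble from [call_presence()].
#' @param annotations Annotation tibble with `protein_id` and the class
#'   column.
#' @param class_column Name of the class column (default `enzyme_class`).
#' @return Tibble `condition`, `class`, `n`, `percent`.
#' @export
class_distribution <- function(presence_calls, annotations,
                               class_column = "enzyme_class") {
  present <- presence_calls[presence_calls$present, ]
  cls <- setNames(annotations[[class_column]], annotations$protein_id)
  present$class <- unname(cls[present$protein_id])
  present$class[is.na(present$class)] <- "unknown"
  out <- dplyr::summarise(
    dplyr::group_by(present, .data$condition, .data$class),
    n = dplyr::n(), .groups = "drop_last"
  )
  out <- dplyr::mutate(out, percent = 100 * .data$n / sum(.data$n))
  dplyr::ungroup(out)
}

#' Join of proteins shared by two proteome fractions
#'
#' Inner join of the secretome and microsome NSAF tables on protein and
#' condition, with NSAF reported on the conventional display scales
#' (secreted NSAF x 10^3, microsomal NSAF x 10^4) and a flag for values
#' increased relative to the control condition within each fraction.
#'
#' @param nsaf_secretome,nsaf_microsome NSAF tibbles from [compute_nsaf()].
#' @param control Control condition name (for the increased flag); `NULL`
#'   omits the flags.
#' @param scale_sec,scale_mic Display multipliers.
#' @return Tibble `protein_id`, `condition`, `nsaf_secreted_e3`,
#'   `nsaf_microsomal_e4`, and `increased_secreted` /
#'   `increased_microsomal` when `control` is given.
#' @export
shared_protein_table <- function(nsaf_secretome, nsaf_microsome,
                                 control = NULL,
                                 scale_sec = 1e3, scale_mic = 1e4) {
  shared <- dplyr::inner_join(
    dplyr::select(nsaf_secretome, "protein_id", "condition",
                  nsaf_sec = "nsaf"),
    dplyr::select(nsaf_microsome, "protein_id", "condition",
                  nsaf_mic = "nsaf"),
    by = c("protein_id", "condition")
  )
  out <- tibble::tibble(
    protein_id = shared$protein_id,
    condition = shared$condition,
    nsaf_secreted_e3 = shared$nsaf_sec * scale_sec,
    nsaf_microsomal_e4 = shared$nsaf_mic * scale_mic
  )
  if (!is.null(control)) {
    ctrl <- shared[shared$condition == control, ]
    ref_sec <- setNames(ctrl$nsaf_sec, ctrl$protein_id)
    ref_mic <- setNames(ctrl$nsaf_mic, ctrl$protein_id)
    out$increased_secreted <- shared$nsaf_sec > ref_sec[shared$protein_id]
    out$increased_microsomal <- shared$nsaf_mic > ref_mic[shared$protein_id]
  }
  out[order(out$protein_id, out$condition), ]
}

#' Run the full analysis pipeline from input files
#'
#' Executes identification (top-hit selection, E-value threshold from the
#' decoy FDR, unique-peptide presence calls), quantification (pooled
#' pseudocounted NSAF over the union presence universe), differential
#' G-tests of each condition against the control, reporting (Venn regions,
#' class distribution, selection summaries) and, when a Ct table is given,
#' Pfaffl qPCR normalization.  Every table is written under fixed
#' subdirectories of `outdir` (`presence/`, `quant/`, `difftest/`,
#' `reports/`, `logs/`) together with a machine-readable JSON run log.
#'
#' @param config Named list (or path to a `key = value` / YAML-like text
#'   file) with entries: `fasta`, `counts`, `control` (required); `psms`,
#'   `annotations`, `ct`, `fdr_target` (default 0.05), `pseudocount`
#'   (default 0.5), `min_g_discussed` (default 10), `seed` (default 1).
#' @param outdir Output directory.
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config(config)
  }
  need <- c("fasta", "counts", "control")
  missing_keys <- setdiff(need, names(config))
  if (length(missing_keys) > 0L) {
    stop("config missing: ", paste(missing_keys, collapse = ", "))
  }
  cfg <- utils::modifyList(
    list(fdr_target = 0.05, pseudocount = 0.5, min_g_discussed = 10,
         seed = 1L, psms = NULL, annotations = NULL, ct = NULL),
    config
  )
  for (d in c("presence", "quant", "difftest", "reports", "logs")) {
    dir.create(file.path(outdir, d), recursive = TRUE, showWarnings = FALSE)
  }
  stage <- "identification"
  result <- tryCatch({
    proteins <- read_fasta(cfg$fasta)
    counts <- read_counts_table(cfg$counts)
    fdr_est <- NULL
    if (!is.null(cfg$psms)) {
      psms <- read_psm_table(cfg$psms, proteins)
      tops <- select_top_hits(psms)
      fdr_est <- select_e_threshold(tops, fdr_target = cfg$fdr_target)
      write_results_table(fdr_est, file.path(outdir, "presence", "fdr.tsv"))
    }
    presence <- call_presence(
      counts[, c("protein_id", "condition", "replicate", "unique_peptides")]
    )
    write_results_table(presence,
                        file.path(outdir, "presence", "presence.tsv"))

    stage <- "quantification"
    universe <- sort(unique(presence$protein_id[presence$present]))
    if (length(universe) == 0L) stop("no proteins called present")
    pooled <- pool_replicates(counts)
    nsaf <- compute_nsaf(pooled, proteins, pseudocount = cfg$pseudocount,
                         universe = universe)
    write_results_table(nsaf, file.path(outdir, "quant", "nsaf.tsv"),
                        digits = 6)

    stage <- "difftest"
    if (!cfg$control %in% counts$condition) {
      stop("control condition '", cfg$control, "' absent from counts")
    }
    diff_res <- test_all_proteins(pooled, nsaf, control = cfg$control,
                                  pseudocount = cfg$pseudocount,
                                  universe = universe)
    write_results_table(diff_res,
                        file.path(outdir, "difftest", "gtest.tsv"),
                        digits = 6)
    selections <- lapply(split(diff_res, diff_res$contrast), function(r) {
      summarize_selection(r, min_g_discussed = cfg$min_g_discussed)
    })
    for (ct_name in names(selections)) {
      safe <- gsub("[^A-Za-z0-9._-]+", "_", ct_name)
      write_results_table(
        selections[[ct_name]]$discussed,
        file.path(outdir, "difftest", paste0("discussed_", safe, ".tsv")),
        digits = 6
      )
    }

    stage <- "reports"
    venn <- venn_counts(presence)
    venn_tbl <- tibble::tibble(region = names(venn$region_counts),
                               n = venn$region_counts)
    write_results_table(venn_tbl, file.path(outdir, "reports", "venn.tsv"))
    classes <- NULL
    if (!is.null(cfg$annotations)) {
      ann <- read_annotation_table(cfg$annotations)
      classes <- class_distribution(presence, ann)
      write_results_table(classes,
                          file.path(outdir, "reports", "class_distribution.tsv"))
    }
    qpcr <- NULL
    if (!is.null(cfg$ct)) {
      stage <- "qpcr"
      ct <- read_ct_table(cfg$ct)
      qpcr <- double_normalize(ct, cfg$control)
      write_results_table(qpcr, file.path(outdir, "reports", "qpcr.tsv"),
                          digits = 6)
      stage <- "reports"
    }
    log <- list(
      parameters = cfg[c("control", "fdr_target", "pseudocount",
                         "min_g_discussed", "seed")],
      inputs = cfg[intersect(names(cfg),
                             c("fasta", "counts", "psms", "annotations", "ct"))],
      n_proteins_db = nrow(proteins),
      n_present_universe = length(universe),
      fdr_estimate = if (is.null(fdr_est)) NULL else as.list(fdr_est)
    )
    jsonlite::write_json(log, file.path(outdir, "logs", "run.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(presence = presence, nsaf = nsaf, differential = diff_res,
         selections = selections, venn = venn, classes = classes,
         qpcr = qpcr, fdr = fdr_est)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); blank lines and
#' `#` comments ignored.  Numeric-looking values are converted.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L) stop("malformed config line ", bad[[1]])
  keys <- trimws(vapply(kv, `[[`, character(1), 2L))
  vals <- trimws(vapply(kv, `[[`, character(1), 3L))
  out <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(out, keys)
}
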