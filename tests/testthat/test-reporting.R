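make_presence <- function(ids, conds, present_map) {
  grid <- tidyr::expand_grid(protein_id = ids, condition = conds)
  grid$present <- mapply(function(p, cond) {
    cond %in% present_map[[p]]
  }, grid$protein_id, grid$condition)
  grid
}

test_that("Venn regions partition the present universe", {
  # 5 proteins: 3 in all, 1 in A only, 1 in A&B
  pm <- list(P1 = c("A", "B", "C"), P2 = c("A", "B", "C"),
             P3 = c("A", "B", "C"), P4 = "A", P5 = c("A", "B"))
  calls <- make_presence(names(pm), c("A", "B", "C"), pm)
  v <- venn_counts(calls)
  expect_equal(v$total, 5L)
  expect_equal(v$region_counts[["A"]], 1L)
  expect_equal(v$region_counts[["A&B"]], 1L)
  expect_equal(v$region_counts[["A&B&C"]], 3L)
  expect_equal(sum(v$region_counts), v$total)
})

test_that("Venn handles degenerate patterns and rejects >3 conditions", {
  all_in <- make_presence(c("P1", "P2"), c("A", "B"),
                          list(P1 = c("A", "B"), P2 = c("A", "B")))
  v <- venn_counts(all_in)
  expect_equal(v$region_counts, c("A&B" = 2L))
  disjoint <- make_presence(c("P1", "P2"), c("A", "B"),
                            list(P1 = "A", P2 = "B"))
  expect_setequal(names(venn_counts(disjoint)$region_counts), c("A", "B"))
  four <- make_presence("P1", c("A", "B", "C", "D"), list(P1 = "A"))
  expect_error(venn_counts(four), "2-3 conditions")
})

test_that("Venn counts agree with brute-force enumeration on random patterns", {
  withr::local_seed(41)
  for (i in 1:10) {
    n <- sample(c(20, 1000), 1)
    ids <- sprintf("P%04d", seq_len(n))
    pm <- lapply(setNames(ids, ids), function(p) {
      sample(c("A", "B", "C"), sample(0:3, 1))
    })
    calls <- make_presence(ids, c("A", "B", "C"), pm)
    v <- venn_counts(calls)
    b <- brute_venn(calls)
    expect_equal(v$total, b$total)
    expect_equal(sum(v$region_counts), v$total)
    expect_equal(v$region_counts[sort(names(v$region_counts))],
                 setNames(as.integer(b$region_counts),
                          names(b$region_counts))[sort(names(b$region_counts))])
  }
})

test_that("class distribution reports percentages over present proteins", {
  pm <- list(P1 = "A", P2 = "A", P3 = "A", P4 = "A", P5 = "A", P6 = "B")
  calls <- make_presence(names(pm), c("A", "B"), pm)
  ann <- tibble::tibble(protein_id = sprintf("P%d", 1:5),
                        enzyme_class = c("hydrolase", "hydrolase",
                                         "hydrolase", "non-enzyme",
                                         "non-enzyme"))
  dist <- class_distribution(calls, ann)
  a <- dist[dist$condition == "A", ]
  expect_equal(a$percent[a$class == "hydrolase"], 60)
  expect_equal(a$percent[a$class == "non-enzyme"], 40)
  # unannotated present protein falls into "unknown"
  b <- dist[dist$condition == "B", ]
  expect_equal(b$class, "unknown")
  expect_equal(b$percent, 100)
  sums <- tapply(dist$percent, dist$condition, sum)
  expect_true(all(abs(sums - 100) < 0.5))
})

test_that("shared-protein table scales NSAF and flags increases vs control", {
  sec <- tibble::tibble(protein_id = rep(c("P1", "P2"), each = 2),
                        condition = rep(c("d-maltose", "d-sorbitol"), 2),
                        spc = 1L, nsaf = c(2e-3, 1e-3, 1e-4, 5e-4))
  mic <- tibble::tibble(protein_id = rep("P1", 2),
                        condition = c("d-maltose", "d-sorbitol"),
                        spc = 1L, nsaf = c(6.39e-3, 7e-3))
  tab <- shared_protein_table(sec, mic, control = "d-sorbitol")
  expect_equal(nrow(tab), 2L)  # P2 absent from the microsome table
  mal <- tab[tab$condition == "d-maltose", ]
  expect_equal(mal$nsaf_microsomal_e4, 63.9)
  expect_equal(mal$nsaf_secreted_e3, 2)
  expect_true(mal$increased_secreted)
  expect_false(mal$increased_microsomal)
  none <- shared_protein_table(sec, mic[0, ], control = "d-sorbitol")
  expect_equal(nrow(none), 0L)
})

local_pipeline_inputs <- function(env = parent.frame()) {
  pr <- generate_proteome(60, seed = 77)
  tr <- generate_truth(pr, n_increased = 2, n_decreased = 10, depth = 2000,
                       seed = 77)
  cts <- simulate_spectral_counts(tr)
  psms <- simulate_psms(n_true = 400, n_false = 400,
                        proteins = make_decoy_db(pr), seed = 77)
  qr <- simulate_qpcr(tibble::tibble(gene = "glaA", condition = "d-maltose",
                                     ratio = 4),
                      control = "d-sorbitol", seed = 77)
  dir <- withr::local_tempdir(.local_envir = env)
  paths <- write_simulation(tr, cts, psms, qr, dir)
  ann <- tibble::tibble(protein_id = pr$protein_id[1:30],
                        signal_peptide = TRUE,
                        enzyme_class = rep(c("hydrolase", "oxidoreductase",
                                             "non-enzyme"), 10))
  paths$annotations <- file.path(dir, "annotations.tsv")
  readr::write_tsv(ann, paths$annotations, progress = FALSE)
  paths
}

test_that("the full pipeline runs end-to-end and its outputs parse", {
  paths <- local_pipeline_inputs()
  out <- withr::local_tempdir()
  res <- run_pipeline(list(fasta = paths$fasta, counts = paths$counts,
                           psms = paths$psms, annotations = paths$annotations,
                           ct = paths$ct, control = "d-sorbitol"),
                      out)
  expect_true(file.exists(file.path(out, "presence", "presence.tsv")))
  expect_true(file.exists(file.path(out, "presence", "fdr.tsv")))
  expect_true(file.exists(file.path(out, "quant", "nsaf.tsv")))
  expect_true(file.exists(file.path(out, "difftest", "gtest.tsv")))
  expect_true(file.exists(file.path(out, "reports", "venn.tsv")))
  expect_true(file.exists(file.path(out, "logs", "run.json")))
  nsaf <- read_results_table(file.path(out, "quant", "nsaf.tsv"))
  sums <- tapply(nsaf$nsaf, nsaf$condition, sum)
  expect_true(all(abs(sums - 1) < 1e-3))  # file precision is 6 significant digits
  log <- jsonlite::read_json(file.path(out, "logs", "run.json"))
  expect_equal(log$parameters$control, "d-sorbitol")
  expect_gt(log$n_present_universe, 0)
  expect_equal(nrow(res$differential),
               2 * log$n_present_universe)
})

test_that("identical config gives byte-identical outputs", {
  paths <- local_pipeline_inputs()
  cfg <- list(fasta = paths$fasta, counts = paths$counts,
              control = "d-sorbitol")
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  run_pipeline(cfg, out1)
  run_pipeline(cfg, out2)
  for (f in c("presence/presence.tsv", "quant/nsaf.tsv",
              "difftest/gtest.tsv", "reports/venn.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("a missing control condition aborts naming the difftest stage", {
  paths <- local_pipeline_inputs()
  counts <- read_counts_table(paths$counts)
  counts <- counts[counts$condition != "d-sorbitol", ]
  p2 <- file.path(dirname(paths$counts), "counts_nocontrol.tsv")
  readr::write_tsv(counts, p2, progress = FALSE)
  out <- withr::local_tempdir()
  expect_error(
    run_pipeline(list(fasta = paths$fasta, counts = p2,
                      control = "d-sorbitol"), out),
    "difftest"
  )
})
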