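# independent likelihood-ratio oracle: iterative proportional fitting via
# stats::loglin, never the package's own G arithmetic
loglin_g <- function(tab) {
  fit <- suppressWarnings(stats::loglin(tab, margin = list(1, 2),
                                        print = FALSE))
  fit$lrt
}

test_that("contingency tables carry pseudocounts and conserve totals", {
  pooled <- tibble::tibble(
    protein_id = rep(c("P1", "P2"), 2),
    condition = rep(c("a", "ctrl"), each = 2),
    spc = c(10L, 10L, 10L, 10L)
  )
  tab <- build_table("P1", pooled, "a", "ctrl", pseudocount = 0.5)
  expect_equal(unname(tab), matrix(10.5, 2, 2))
  # zero-count protein floors at the pseudocount; remainder is total - a
  pooled2 <- tibble::tibble(protein_id = c("P1", "P2", "P2"),
                            condition = c("a", "a", "ctrl"),
                            spc = c(7L, 3L, 12L))
  tab2 <- build_table("P1", pooled2, "a", "ctrl", pseudocount = 0.5,
                      universe = c("P1", "P2"))
  expect_equal(tab2["ctrl", "protein"], 0.5)
  expect_equal(tab2["a", "protein"] + tab2["a", "rest"], 7 + 3 + 2 * 0.5)
  expect_error(build_table("P9", pooled, "a", "ctrl"), "not in universe")
})

test_that("G statistic matches the direct formula and the loglin oracle", {
  tab <- matrix(c(10, 90, 2, 98), nrow = 2, byrow = TRUE)
  manual <- 2 * (10 * log(10 / 6) + 90 * log(90 / 94) +
                   2 * log(2 / 6) + 98 * log(98 / 94))
  expect_equal(g_statistic(tab), manual, tolerance = 1e-12)
  expect_equal(g_statistic(tab), loglin_g(tab), tolerance = 1e-9)
  expect_equal(g_statistic(t(tab)), g_statistic(tab), tolerance = 1e-12)
})

test_that("G is zero iff rows are proportional and agrees with loglin on random tables", {
  expect_equal(g_statistic(matrix(c(5, 15, 10, 30), 2, byrow = TRUE)), 0,
               tolerance = 1e-12)
  withr::local_seed(123)
  for (i in 1:1000) {
    tab <- matrix(rpois(4, lambda = sample(c(2, 20, 200), 1)) + 0.5, 2, 2)
    expect_lt(abs(g_statistic(tab) - loglin_g(tab)), 1e-9)
    expect_gte(g_statistic(tab), 0)
  }
})

test_that("G converges to the Pearson chi-square for large expected counts", {
  withr::local_seed(9)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 5000) + 1000, 2, 2)  # all expected cells >= 500
    g <- g_statistic(tab)
    x2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
    if (g > 1e-6) expect_lt(abs(g - x2) / max(x2, g), 0.01)
  }
})

test_that("chi-square tail and critical values match the published thresholds", {
  expect_equal(chi2_sf(0, 1), 1)
  expect_lt(abs(chi2_sf(3.841, 1) - 0.05), 5e-4)
  expect_lt(abs(chi2_sf(10.828, 1) - 0.001), 5e-5)
  expect_equal(round(g_critical(0.05, 1), 3), 3.841)
  expect_equal(round(g_critical(0.001, 1), 3), 10.828)
})

test_that("test_protein reports direction from NSAF and zero G for equal distributions", {
  pooled <- tibble::tibble(
    protein_id = rep(c("P1", "P2"), 2),
    condition = rep(c("a", "ctrl"), each = 2),
    spc = c(10L, 10L, 10L, 10L)
  )
  nsaf <- compute_nsaf(pooled, c(P1 = 100L, P2 = 100L))
  r <- test_protein("P1", pooled, nsaf, "a", "ctrl")
  expect_equal(r$g_score, 0, tolerance = 1e-12)
  expect_false(r$significant_05)
  expect_equal(r$direction, "increased")  # exact tie reported as increased
  pooled2 <- tibble::tibble(
    protein_id = rep(c("P1", "P2"), 2),
    condition = rep(c("a", "ctrl"), each = 2),
    spc = c(50L, 10L, 10L, 50L)
  )
  nsaf2 <- compute_nsaf(pooled2, c(P1 = 100L, P2 = 100L))
  r2 <- test_protein("P1", pooled2, nsaf2, "a", "ctrl")
  expect_equal(r2$direction, "increased")
  expect_true(r2$significant_05)
  expect_equal(r2$p_value, chi2_sf(r2$g_score, 1))
  r3 <- test_protein("P2", pooled2, nsaf2, "a", "ctrl")
  expect_equal(r3$direction, "decreased")
})

test_that("significance flags are consistent with the chi-square tail", {
  pr <- generate_proteome(60, seed = 17)
  tr <- generate_truth(pr, n_increased = 1, n_decreased = 5, depth = 2000,
                       seed = 17)
  cts <- simulate_spectral_counts(tr)
  pooled <- pool_replicates(cts)
  nsaf <- compute_nsaf(pooled, pr)
  res <- test_all_proteins(pooled, nsaf, control = tr$control)
  expect_equal(res$significant_05,
               res$p_value <= chi2_sf(3.841, 1) + 1e-12)
  expect_equal(res$significant_001,
               res$p_value <= chi2_sf(10.828, 1) + 1e-12)
  # vectorized driver agrees with the single-protein route
  one <- test_protein(res$protein_id[5], pooled, nsaf,
                      "d-maltose", tr$control)
  row <- res[res$protein_id == one$protein_id &
               res$contrast == one$contrast, ]
  expect_equal(row$g_score, one$g_score, tolerance = 1e-12)
  expect_equal(row$direction, one$direction)
})

test_that("counts and NSAF-rescaled constructions coincide for equal lengths", {
  pr <- generate_proteome(30, length_log_sd = 0, seed = 23)
  tr <- generate_truth(pr, n_increased = 1, n_decreased = 5, depth = 1500,
                       seed = 23)
  cts <- simulate_spectral_counts(tr)
  pooled <- pool_replicates(cts)
  nsaf <- compute_nsaf(pooled, pr)
  a <- test_all_proteins(pooled, nsaf, control = tr$control,
                         rescale = "counts")
  b <- test_all_proteins(pooled, nsaf, control = tr$control,
                         rescale = "nsaf")
  expect_equal(a$g_score, b$g_score, tolerance = 1e-9)
})

test_that("selection summary applies G > 10 and ceiling top fractions", {
  res <- tibble::tibble(
    protein_id = sprintf("P%02d", 1:12),
    contrast = "a vs ctrl",
    g_score = c(25, 20, 15, 12, 11, 8, 6, 5, 30, 18, 9, 2),
    p_value = chi2_sf(g_score, 1),
    direction = c(rep("increased", 8), rep("decreased", 4)),
    significant_05 = g_score >= 3.841,
    significant_001 = g_score >= 10.828
  )
  sel <- summarize_selection(res)
  # 8 significant increased -> ceiling(8 * 0.25) = 2
  expect_equal(sel$n_significant_increased, 8L)
  expect_equal(nrow(sel$top_increased), 2L)
  expect_equal(sel$top_increased$protein_id, c("P01", "P02"))
  # 3 significant decreased -> ceiling(3 * 0.10) = 1, highest G first
  expect_equal(sel$n_significant_decreased, 3L)
  expect_equal(sel$top_decreased$protein_id, "P09")
  # discussion set: significant AND G > 10 regardless of direction
  expect_setequal(sel$discussed$protein_id,
                  c("P01", "P02", "P03", "P04", "P05", "P09", "P10"))
  empty <- summarize_selection(res[res$g_score < 3, ])
  expect_equal(nrow(empty$discussed), 0L)
  expect_equal(nrow(empty$top_increased), 0L)
})
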