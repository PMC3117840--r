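#' G-score significance thresholds (chi-square, df = 1)
#'
#' G >= 3.841 corresponds to P < 0.05 and G >= 10.828 to P < 0.001 under
#' the chi-square distribution with one degree of freedom.
#'
#' @format Named numeric vector with elements `p05` and `p001`.
#' @export
G_THRESHOLDS <- c(p05 = 3.841, p001 = 10.828)

#' Upper-tail chi-square probability
#'
#' @param x Non-negative statistic value.
#' @param df Degrees of freedom (>= 1).
#' @return P(X >= x) for X ~ chi-square(df).
#' @export
chi2_sf <- function(x, df = 1) {
  stopifnot(all(x >= 0), df >= 1)
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Chi-square critical value for an upper-tail probability
#'
#' The G score whose upper-tail probability equals `alpha`; at df = 1,
#' `g_critical(0.05)` is 3.841 and `g_critical(0.001)` is 10.828.
#'
#' @param alpha Upper-tail probability in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return Critical value.
#' @export
g_critical <- function(alpha, df = 1) {
  stopifnot(all(alpha > 0), all(alpha < 1), df >= 1)
  stats::qchisq(alpha, df = df, lower.tail = FALSE)
}

#' Pseudocounted 2x2 contingency table for one protein
#'
#' Rows are conditions (test, control); columns split the condition total
#' into the protein's pseudocounted count and the remainder over the rest
#' of the universe:
#' a = SpC + c in the test condition, c' = SpC + c in the control, and
#' b, d are the condition/control totals (sum over the universe of
#' SpC + c) minus a and c'.  Totals are computed over the same universe and
#' with the same pseudocount as NSAF.
#'
#' @param protein_id Protein to test.
#' @param pooled_counts Tibble from [pool_replicates()].
#' @param condition,control Test and control condition names.
#' @param pseudocount Pseudocount c (default 0.5).
#' @param universe Normalization universe (defaults to proteins in
#'   `pooled_counts`).
#' @return 2x2 numeric matrix with dimnames condition x (protein, rest).
#' @export
build_table <- function(protein_id, pooled_counts, condition, control,
                        pseudocount = 0.5, universe = NULL) {
  if (is.null(universe)) universe <- unique(pooled_counts$protein_id)
  if (!protein_id %in% universe) {
    stop("protein ", protein_id, " not in universe")
  }
  get <- function(cond) {
    sub <- pooled_counts[pooled_counts$condition == cond &
                           pooled_counts$protein_id %in% universe, ]
    total <- sum(sub$spc) + pseudocount * length(universe)
    own <- sub$spc[sub$protein_id == protein_id]
    own <- (if (length(own) == 0L) 0 else own) + pseudocount
    c(own = own, rest = total - own)
  }
  a <- get(condition)
  b <- get(control)
  matrix(c(a, b), nrow = 2, byrow = TRUE,
         dimnames = list(c(condition, control), c("protein", "rest")))
}

#' Likelihood-ratio G statistic for a contingency table
#'
#' G = 2 * sum over cells of O * ln(O / E), with expected counts E from the
#' product of row and column marginals over the grand total; zero observed
#' cells contribute nothing.  No continuity correction is applied by
#' default; `williams = TRUE` divides G by the Williams correction factor
#' q = 1 + (n/R - 1)(n/C - 1) / (6 n (r-1)(c-1)) for conservative small
#' samples.
#'
#' @param table Non-negative numeric matrix (typically 2x2 from
#'   [build_table()]).
#' @param williams Apply the Williams correction.
#' @return Non-negative G score; 0 iff rows are exactly proportional.
#' @export
g_statistic <- function(table, williams = FALSE) {
  O <- as.matrix(table)
  if (any(O < 0)) stop("negative cell in contingency table")
  rs <- rowSums(O)
  cs <- colSums(O)
  n <- sum(O)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal in contingency table")
  E <- outer(rs, cs) / n
  terms <- ifelse(O > 0, O * log(O / E), 0)
  G <- 2 * sum(terms)
  if (williams) {
    q <- 1 + (sum(n / rs) - 1) * (sum(n / cs) - 1) /
      (6 * n * (nrow(O) - 1) * (ncol(O) - 1))
    G <- G / q
  }
  max(G, 0)
}

#' G-test of one protein against the control condition
#'
#' Builds the pseudocounted 2x2 table, computes the G statistic and its
#' chi-square (df = 1) p-value, and assigns the direction of change from
#' the NSAF comparison: increased iff NSAF(condition) > NSAF(control)
#' (exact ties are reported as increased with G = 0).
#'
#' With `rescale = "nsaf"` the table is built from NSAF values multiplied
#' by the pseudocounted condition totals instead of the raw pseudocounted
#' counts, i.e. the test is applied to length-normalized abundance; the
#' two constructions coincide exactly when all protein lengths are equal.
#'
#' @inheritParams build_table
#' @param nsaf NSAF tibble from [compute_nsaf()].
#' @param williams Apply the Williams correction to G.
#' @param rescale `"counts"` (default) or `"nsaf"`.
#' @return One-row tibble: `protein_id`, `contrast`, `g_score`, `p_value`,
#'   `direction`, `significant_05`, `significant_001`.
#' @export
test_protein <- function(protein_id, pooled_counts, nsaf, condition, control,
                         pseudocount = 0.5, universe = NULL,
                         williams = FALSE,
                         rescale = c("counts", "nsaf")) {
  rescale <- match.arg(rescale)
  if (is.null(universe)) universe <- unique(pooled_counts$protein_id)
  tab <- build_table(protein_id, pooled_counts, condition, control,
                     pseudocount, universe)
  if (rescale == "nsaf") {
    for (i in 1:2) {
      cond <- rownames(tab)[i]
      total <- sum(tab[i, ])
      v <- nsaf$nsaf[nsaf$condition == cond & nsaf$protein_id == protein_id]
      tab[i, ] <- c(v, 1 - v) * total
    }
  }
  g <- g_statistic(tab, williams = williams)
  n1 <- nsaf$nsaf[nsaf$condition == condition & nsaf$protein_id == protein_id]
  n0 <- nsaf$nsaf[nsaf$condition == control & nsaf$protein_id == protein_id]
  tibble::tibble(
    protein_id = protein_id,
    contrast = paste(condition, "vs", control),
    g_score = g,
    p_value = chi2_sf(g, 1),
    direction = if (n1 >= n0) "increased" else "decreased",
    significant_05 = g >= G_THRESHOLDS[["p05"]],
    significant_001 = g >= G_THRESHOLDS[["p001"]]
  )
}

#' G-tests of every universe protein, each induction condition vs control
#'
#' Vectorized driver over [test_protein()]'s arithmetic: one 2x2 G-test per
#' (protein, contrast) with the shared pseudocounted totals.  An optional
#' Benjamini-Hochberg adjusted p-value column can be added, but
#' significance flags always follow the fixed G thresholds.
#'
#' @inheritParams test_protein
#' @param conditions Test conditions; defaults to all non-control
#'   conditions present in `pooled_counts`.
#' @param bh_adjust Add a `p_adj` column (Benjamini-Hochberg within each
#'   contrast).
#' @return Tibble of per-protein results, one row per (protein, contrast).
#' @export
test_all_proteins <- function(pooled_counts, nsaf, control,
                              conditions = NULL, pseudocount = 0.5,
                              universe = NULL, williams = FALSE,
                              rescale = c("counts", "nsaf"),
                              bh_adjust = FALSE) {
  rescale <- match.arg(rescale)
  if (is.null(universe)) universe <- sort(unique(pooled_counts$protein_id))
  if (is.null(conditions)) {
    conditions <- setdiff(sort(unique(pooled_counts$condition)), control)
  }
  if (!control %in% pooled_counts$condition) {
    stop("control condition '", control, "' absent from counts")
  }
  spc_of <- function(cond) {
    sub <- pooled_counts[pooled_counts$condition == cond, ]
    v <- setNames(rep(0, length(universe)), universe)
    v[sub$protein_id[sub$protein_id %in% universe]] <-
      sub$spc[sub$protein_id %in% universe]
    v + pseudocount
  }
  nsaf_of <- function(cond) {
    sub <- nsaf[nsaf$condition == cond, ]
    setNames(sub$nsaf, sub$protein_id)[universe]
  }
  ctrl_counts <- spc_of(control)
  ctrl_total <- sum(ctrl_counts)
  ctrl_nsaf <- nsaf_of(control)
  res <- lapply(conditions, function(cond) {
    test_counts <- spc_of(cond)
    test_total <- sum(test_counts)
    test_nsaf <- nsaf_of(cond)
    if (rescale == "nsaf") {
      a <- test_nsaf * test_total
      cc <- ctrl_nsaf * ctrl_total
    } else {
      a <- test_counts
      cc <- ctrl_counts
    }
    g <- vapply(seq_along(universe), function(i) {
      g_statistic(matrix(c(a[i], test_total - a[i],
                           cc[i], ctrl_total - cc[i]),
                         nrow = 2, byrow = TRUE), williams = williams)
    }, numeric(1))
    out <- tibble::tibble(
      protein_id = universe,
      contrast = paste(cond, "vs", control),
      g_score = g,
      p_value = chi2_sf(g, 1),
      direction = unname(ifelse(test_nsaf >= ctrl_nsaf,
                                "increased", "decreased")),
      significant_05 = g >= G_THRESHOLDS[["p05"]],
      significant_001 = g >= G_THRESHOLDS[["p001"]]
    )
    if (bh_adjust) out$p_adj <- stats::p.adjust(out$p_value, "BH")
    out
  })
  dplyr::bind_rows(res)
}

#' Selection summary of differential proteins for one contrast
#'
#' Partitions significant results (G >= 3.841) by direction and reports
#' (i) every protein with G above `min_g_discussed` (the discussion set)
#' and (ii) the top `frac_increased` of the significantly increased and top
#' `frac_decreased` of the significantly decreased proteins ranked by
#' descending G.  Top-fraction sizes use ceiling rounding; ties in G are
#' broken by protein identifier.
#'
#' @param results Result tibble for a single contrast.
#' @param min_g_discussed G cutoff for the discussion set.
#' @param frac_increased,frac_decreased Top fractions in `[0, 1]`.
#' @return List with tibbles `discussed`, `top_increased`, `top_decreased`
#'   and the counts `n_significant_increased`, `n_significant_decreased`.
#' @export
summarize_selection <- function(results, min_g_discussed = 10,
                                frac_increased = 0.25,
                                frac_decreased = 0.10) {
  if (length(unique(results$contrast)) > 1L) {
    stop("summarize_selection expects results for a single contrast")
  }
  sig <- results[results$significant_05, ]
  sig <- sig[order(-sig$g_score, sig$protein_id), ]
  inc <- sig[sig$direction == "increased", ]
  dec <- sig[sig$direction == "decreased", ]
  top_n <- function(x, frac) {
    if (nrow(x) == 0L) return(x[0, ])
    utils::head(x, ceiling(nrow(x) * frac))
  }
  list(
    discussed = sig[sig$g_score > min_g_discussed, ],
    top_increased = top_n(inc, frac_increased),
    top_decreased = top_n(dec, frac_decreased),
    n_significant_increased = nrow(inc),
    n_significant_decreased = nrow(dec)
  )
}
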