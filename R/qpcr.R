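#' Pfaffl efficiency-corrected expression ratio
#'
#' ratio = eff_target^dCt_target / eff_ref^dCt_ref, where each dCt is
#' Ct(calibrator) - Ct(sample) and the efficiencies are fold amplification
#' per cycle (2 for perfect doubling).
#'
#' @param eff_target,eff_ref Amplification efficiencies in (1, 2].
#' @param delta_ct_target,delta_ct_ref Cycle differences
#'   Ct(calibrator) - Ct(sample) for the target gene and the reference.
#' @return Positive expression ratio.
#' @export
pfaffl_ratio <- function(eff_target, delta_ct_target, eff_ref, delta_ct_ref) {
  if (any(eff_target <= 1 | eff_target > 2) ||
      any(eff_ref <= 1 | eff_ref > 2)) {
    stop("efficiencies must lie in (1, 2]")
  }
  eff_target^delta_ct_target / eff_ref^delta_ct_ref
}

#' Double-normalized relative expression (spike, then control condition)
#'
#' Per replicate, expression is first normalized to the exogenous spike
#' transcript via the Pfaffl ratio (the spike is the reference gene), then
#' divided by the average of the control condition's spike-normalized
#' values for that gene, so the control condition averages to 1.  Averaging
#' uses the geometric mean by default — expression ratios are
#' multiplicative — with the arithmetic mean available via `average`.
#'
#' @param ct_records Ct tibble (schema of [read_ct_table()]).
#' @param control_condition Name of the control condition.
#' @param average `"geometric"` (default) or `"arithmetic"` control mean.
#' @return Tibble `gene`, `condition`, `replicate`, `ratio`,
#'   `log10_ratio`.
#' @export
double_normalize <- function(ct_records, control_condition,
                             average = c("geometric", "arithmetic")) {
  average <- match.arg(average)
  need <- c("gene", "condition", "replicate", "ct_target", "ct_spike",
            "eff_target", "eff_spike")
  stopifnot(all(need %in% names(ct_records)))
  if (!control_condition %in% ct_records$condition) {
    stop("control condition '", control_condition, "' absent from Ct table")
  }
  if (any(is.na(ct_records$ct_target)) || any(is.na(ct_records$ct_spike))) {
    stop("missing Ct value")
  }
  out <- lapply(split(ct_records, ct_records$gene), function(g) {
    ctrl <- g[g$condition == control_condition, ]
    if (nrow(ctrl) == 0L) {
      stop("gene ", g$gene[[1]], " lacks control-condition records")
    }
    # spike-normalized expression per replicate, with the mean control Cts
    # as the Pfaffl calibrator (the calibrator choice cancels in the final
    # double-normalized ratio)
    v <- pfaffl_ratio(g$eff_target, mean(ctrl$ct_target) - g$ct_target,
                      g$eff_spike, mean(ctrl$ct_spike) - g$ct_spike)
    v_ctrl <- v[g$condition == control_condition]
    denom <- if (average == "geometric") {
      exp(mean(log(v_ctrl)))
    } else {
      mean(v_ctrl)
    }
    tibble::tibble(
      gene = g$gene, condition = g$condition, replicate = g$replicate,
      ratio = v / denom, log10_ratio = log10(v / denom)
    )
  })
  dplyr::bind_rows(out)
}

#' Condition-level summary of relative expression
#'
#' Geometric mean ratio and its log10 per (gene, condition) over
#' replicates, the form in which relative expression is plotted on a
#' logarithmic scale.
#'
#' @param relative_expression Output of [double_normalize()].
#' @return Tibble `gene`, `condition`, `n`, `ratio`, `log10_ratio`,
#'   `se_log10` (standard error of the log10 ratios).
#' @export
summarize_expression <- function(relative_expression) {
  dplyr::summarise(
    dplyr::group_by(relative_expression, .data$gene, .data$condition),
    n = dplyr::n(),
    ratio = exp(mean(log(.data$ratio))),
    log10_ratio = mean(.data$log10_ratio),
    se_log10 = stats::sd(.data$log10_ratio) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}
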