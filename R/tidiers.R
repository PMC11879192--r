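#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a group comparison
#'
#' @param x A `group_comparison` from [group_compare()].
#' @param ... Unused.
#' @return One row per group: `column`, `group`, `n`, `median`, `q25`, `q75`.
#' @export
tidy.group_comparison <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(column = x$column), x$summary)
}

#' @rdname tidy.group_comparison
#' @return `glance()`: a one-row tibble with `column`, `statistic`,
#'   `p_value`, `method`.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(column = x$column, statistic = x$statistic,
                 p_value = x$p_value, method = x$method)
}

#' Tidy a ROC result
#'
#' @param x A `roc_result` from [roc_analysis()].
#' @param ... Unused.
#' @return `tidy()`: one row per operating threshold (`threshold`,
#'   `sensitivity`, `specificity`, `youden_j`).
#' @export
tidy.roc_result <- function(x, ...) x$thresholds

#' @rdname tidy.roc_result
#' @return `glance()`: a one-row tibble with the AUC, its bootstrap CI,
#'   direction and the Youden operating point.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    column = x$column, auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
    direction = x$direction, youden_cutoff = x$youden_cutoff,
    sensitivity = x$sensitivity, specificity = x$specificity,
    n_boot = x$n_boot
  )
}

#' Tidy an AUC comparison
#'
#' @param x An `auc_comparison` from [compare_auc()].
#' @param ... Unused.
#' @return A one-row tibble with both AUCs, their difference, the bootstrap
#'   percentile CI and the two-sided bootstrap p-value.
#' @export
tidy.auc_comparison <- function(x, ...) {
  tibble::tibble(
    column_a = x$column_a, column_b = x$column_b,
    auc_a = x$auc_a, auc_b = x$auc_b, delta_auc = x$delta_auc,
    ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
    n_boot = x$n_boot
  )
}

#' Tidy a reliability result
#'
#' @param x A `reliability_result` from [icc_single()].
#' @param ... Unused.
#' @return A one-row tibble with `icc`, `ci_low`, `ci_high`, `model`, `sem`,
#'   `n_subjects`.
#' @export
tidy.reliability_result <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
    model = x$model, sem = x$sem, n_subjects = x$n_subjects
  )
}

#' Tidy a full analysis report
#'
#' @param x A `dyssync_report` from [run_full_analysis()].
#' @param ... Unused.
#' @return `tidy()`: the per-subject index tibble. `glance()`: a one-row
#'   tibble with the headline results (group medians, rank-test p-values,
#'   AUCs, the AUC contrast and the odds ratios).
#' @export
tidy.dyssync_report <- function(x, ...) x$indices

#' @rdname tidy.dyssync_report
#' @export
glance.dyssync_report <- function(x, ...) {
  med <- function(ix, g) {
    s <- x$group_comparisons[[ix]]$summary
    s$median[s$group == g]
  }
  tibble::tibble(
    n_lbbb = sum(x$indices$group == "LBBB"),
    n_control = sum(x$indices$group == "control"),
    cure_median_lbbb = med("cure", "LBBB"),
    cure_median_control = med("cure", "control"),
    cure_p = x$group_comparisons$cure$p_value,
    ssi_median_lbbb = med("ssi", "LBBB"),
    ssi_median_control = med("ssi", "control"),
    ssi_p = x$group_comparisons$ssi$p_value,
    auc_cure = x$roc$cure$auc,
    auc_ssi = x$roc$ssi$auc,
    delta_auc = x$auc_comparison$delta_auc,
    delta_auc_p = x$auc_comparison$p_value,
    or_ssi = x$odds_ratios$or[x$odds_ratios$column == "ssi"],
    or_cure = x$odds_ratios$or[x$odds_ratios$column == "cure"]
  )
}
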