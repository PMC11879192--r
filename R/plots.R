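#' Plot segmental strain curves
#'
#' Spaghetti plot of the six segmental circumferential strain curves per
#' subject, with the aortic valve opening/closure frames marked. The LBBB
#' signature is visible as septal early shortening with rebound stretch and
#' lateral pre-stretch with delayed shortening.
#'
#' @param cohort A [strain_cohort()].
#' @param subjects Subject ids to plot (default: first subject of each group).
#' @return A ggplot object.
#' @export
plot_strain_curves <- function(cohort, subjects = NULL) {
  stopifnot(inherits(cohort, "strain_cohort"))
  if (is.null(subjects)) {
    subjects <- cohort$strain |>
      dplyr::distinct(.data$subject_id, .data$group) |>
      dplyr::slice_head(n = 1, by = "group") |>
      dplyr::pull("subject_id")
  }
  df <- cohort$strain |>
    dplyr::filter(.data$subject_id %in% subjects) |>
    dplyr::mutate(segment = factor(.data$segment, levels = SEGMENTS))
  ev <- cohort$events |>
    dplyr::filter(.data$subject_id %in% subjects) |>
    tidyr::pivot_longer(dplyr::all_of(c("avo_frame", "avc_frame")),
                        names_to = "event", values_to = "frame")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$strain_pct,
                                   colour = .data$segment)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_vline(data = ev,
                        ggplot2::aes(xintercept = .data$frame,
                                     linetype = .data$event),
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(x = "frame", y = "circumferential strain (%)",
                  colour = "segment", linetype = "event") +
    ggplot2::theme_minimal()
}

#' Box-and-whisker plots of indices by group
#'
#' Distribution of each dyssynchrony index per group: box spans the
#' interquartile range, horizontal line is the median, whiskers extend to
#' data within 1.5 IQR of the quartiles, all points overlaid.
#'
#' @param indices Per-subject index tibble from [compute_indices()].
#' @param columns Index columns to show (default CURE and SSI).
#' @return A ggplot object.
#' @export
plot_index_distributions <- function(indices, columns = c("cure", "ssi")) {
  df <- indices |>
    tidyr::pivot_longer(dplyr::all_of(columns), names_to = "index",
                        values_to = "value") |>
    dplyr::mutate(index = toupper(.data$index))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' Plots sensitivity against 1 - specificity over all operating thresholds,
#' marking the Youden-index operating point, with the AUC and its bootstrap
#' CI in the subtitle. `plot_roc()` is an alias for `autoplot()`.
#'
#' @param object A `roc_result` from [roc_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.roc_result <- function(object, ...) {
  x <- object
  thr <- x$thresholds[order(1 - x$thresholds$specificity,
                            x$thresholds$sensitivity), ]
  ggplot2::ggplot(thr, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::annotate("point", x = 1 - x$specificity, y = x$sensitivity,
                      shape = 21, size = 3, fill = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = paste0("ROC: ", toupper(x$column)),
      subtitle = sprintf("AUC %.2f (95%% CI %.2f-%.2f)",
                         x$auc, x$ci_low, x$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.roc_result
#' @export
plot_roc <- function(object, ...) autoplot.roc_result(object, ...)
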