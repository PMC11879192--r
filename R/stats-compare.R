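#' Compare an index between groups (median, IQR, rank test)
#'
#' Summarises one per-subject index as median (interquartile range) per group
#' and compares the two independent groups with the two-sided Wilcoxon
#' rank-sum (Mann--Whitney) test: exact when the combined sample size is at
#' most 30 and there are no ties, otherwise the normal approximation with
#' continuity and tie correction. Quantiles use linear interpolation between
#' order statistics (type 7).
#'
#' @param table A data frame with a `group` column (`"LBBB"` / `"control"`)
#'   and the index column, e.g. the output of [compute_indices()].
#' @param column Name of the index column to compare (string).
#' @return An object of class `group_comparison`: a list with `column`,
#'   `summary` (tibble: `group`, `n`, `median`, `q25`, `q75`), `statistic`
#'   (the Mann--Whitney U for the first group), `p_value` and `method`.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_params(n_lbbb = 10, n_control = 10))
#' group_compare(compute_indices(cohort), "ssi")
group_compare <- function(table, column) {
  check_two_groups(table, column)
  x <- table[[column]]
  g <- factor(table$group, levels = intersect(GROUP_LEVELS,
                                              unique(table$group)))
  if (any(tapply(x, g, length) < 2)) {
    abort("each group must contain at least 2 subjects")
  }
  summary <- tibble::tibble(
    group = levels(g),
    n = as.integer(table(g)),
    median = as.numeric(tapply(x, g, median)),
    q25 = as.numeric(tapply(x, g, quantile, probs = 0.25, type = 7)),
    q75 = as.numeric(tapply(x, g, quantile, probs = 0.75, type = 7))
  )
  x1 <- x[g == levels(g)[1]]
  x2 <- x[g == levels(g)[2]]
  ties <- anyDuplicated(x) > 0
  exact <- (length(x) <= 30) && !ties
  wt <- suppressWarnings(
    wilcox.test(x1, x2, exact = exact, correct = TRUE)
  )
  structure(
    list(column = column, summary = summary,
         statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (exact) "exact Wilcoxon rank-sum" else
           "Wilcoxon rank-sum, normal approximation with continuity correction"),
    class = "group_comparison"
  )
}

check_two_groups <- function(table, column) {
  if (!column %in% names(table)) {
    abort(paste0("column '", column, "' not found in table"))
  }
  if (!"group" %in% names(table)) abort("table must have a `group` column")
  if (anyNA(table[[column]])) {
    abort(paste0("column '", column, "' contains missing values"))
  }
  if (length(unique(table$group)) < 2) {
    abort("both groups must be present")
  }
  invisible(TRUE)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$column, "\n", sep = "")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-8s n=%-3d %s\n", s$group, s$n,
                fmt_median_iqr(s$median, s$q25, s$q75)))
  }
  cat("  ", x$method, ": U = ", format(x$statistic),
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Spearman's rho computed on midranks (ties averaged), with the p-value from
#' [stats::cor.test()]'s Spearman method (exact for small untied samples,
#' t approximation otherwise). Used e.g. to relate dyssynchrony indices to
#' QRS duration.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A tibble with columns `rho` and `p_value`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Spearman's rho is undefined for a constant input")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Univariable logistic odds ratio on a reporting unit scale
#'
#' Fits the single-predictor logistic regression `P(group = LBBB) ~ index`
#' by maximum likelihood and reports the odds ratio per `unit` change of the
#' predictor: `OR = exp(unit * beta)`, with the Wald 95% confidence interval
#' transformed to the same scale. A negative `unit` expresses "per `|unit|`
#' decrease" (e.g. `unit = -0.10` for CURE, so the OR is per 0.10-decrease);
#' the interval is re-ordered so `ci_low <= ci_high`.
#'
#' @param table A data frame with `group` and the index column.
#' @param column Predictor column name (string).
#' @param unit Reporting unit for the odds ratio (default `1`).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with columns `column`, `unit`, `or`, `ci_low`, `ci_high`,
#'   `beta`, `se`, `p_value`.
#' @export
logistic_or <- function(table, column, unit = 1, conf_level = 0.95) {
  check_two_groups(table, column)
  if (unit == 0) abort("`unit` must be nonzero")
  y <- as.integer(table$group == "LBBB")
  x <- table[[column]]
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  mu <- fit$fitted.values
  if (!fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8)) {
    ## complete or quasi-complete separation: the MLE diverges
    abort(paste0(
      "logistic model for '", column, "' did not converge to a finite ",
      "odds ratio (perfect separation)"
    ))
  }
  beta <- unname(coef(fit)["x"])
  se <- sqrt(diag(vcov(fit)))[["x"]]
  z <- qnorm(1 - (1 - conf_level) / 2)
  lo <- exp(unit * (beta - z * se))
  hi <- exp(unit * (beta + z * se))
  tibble::tibble(
    column = column, unit = unit,
    or = exp(unit * beta),
    ci_low = min(lo, hi), ci_high = max(lo, hi),
    beta = beta, se = se,
    p_value = 2 * pnorm(-abs(beta / se))
  )
}

fmt_median_iqr <- function(m, q25, q75, digits = 2) {
  paste0(signif(m, digits), " (", signif(q25, digits), "-",
         signif(q75, digits), ")")
}
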