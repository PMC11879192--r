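#' Intraclass correlation for single measures, with SEM
#'
#' Quantifies rater agreement for a dyssynchrony index from a subjects-by-2
#' ratings matrix using the two-way ANOVA mean squares. Two single-measure
#' (k = 1) models are available: `two_way_random_absolute_single` — ICC(2,1),
#' absolute agreement, raters treated as a random sample (the inter-rater
#' model) — and `two_way_fixed_single` — ICC(3,1), consistency, raters fixed
#' (the intra-rater model). 95% confidence intervals are F-based
#' (Shrout--Fleiss / McGraw--Wong). Absolute reliability is reported as the
#' standard error of measurement, `SEM = sqrt(MS_error)` from the two-way
#' ANOVA, in the units of the measurements.
#'
#' @param ratings A numeric matrix or data frame with one row per subject and
#'   exactly 2 rating columns (no missing cells), or a long data frame with
#'   columns `subject_id`, `rater`, `value`.
#' @param model `"two_way_random_absolute_single"` (default) or
#'   `"two_way_fixed_single"`.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `reliability_result`: list with `icc`,
#'   `ci_low`, `ci_high`, `model`, `sem`, `n_subjects`, `n_raters` and the
#'   mean squares `ms` (rows, columns, error).
#' @export
#' @examples
#' set.seed(1)
#' truth <- rnorm(12, 10, 3)
#' r <- cbind(truth + rnorm(12, 0, 1), truth + rnorm(12, 0, 1))
#' icc_single(r)
icc_single <- function(ratings,
                       model = c("two_way_random_absolute_single",
                                 "two_way_fixed_single"),
                       conf_level = 0.95) {
  model <- match.arg(model)
  m <- as_ratings_matrix(ratings)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5) abort("need at least 5 subjects for a reliability estimate")
  if (k != 2) abort("exactly 2 raters/readings are required")
  if (anyNA(m)) abort("ratings must have no missing cells")

  ## two-way ANOVA mean squares (subjects x raters, one observation per cell)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((m - outer(row_m, rep(1, k)) -
                   outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  if (msr <= .Machine$double.eps * abs(grand + 1)) {
    abort("zero between-subject variance: ICC is degenerate")
  }

  alpha <- 1 - conf_level
  if (mse == 0) {
    ## perfect within-subject agreement: the F-based intervals degenerate
    icc <- if (model == "two_way_fixed_single") 1 else {
      (msr) / (msr + k * msc / n)
    }
    return(structure(
      list(icc = icc, ci_low = icc, ci_high = icc, model = model,
           sem = 0, n_subjects = n, n_raters = k,
           ms = c(rows = msr, cols = msc, error = mse)),
      class = "reliability_result"
    ))
  }
  if (model == "two_way_fixed_single") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    ## McGraw & Wong F-based interval with Satterthwaite df
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    f2u <- qf(1 - alpha / 2, n - 1, v)
    f2l <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f2u * mse) /
      (f2u * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2l * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2l * msr)
    ci <- c(lo, hi)
  }

  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2], model = model,
         sem = sqrt(mse), n_subjects = n, n_raters = k,
         ms = c(rows = msr, cols = msc, error = mse)),
    class = "reliability_result"
  )
}

as_ratings_matrix <- function(ratings) {
  if (is.data.frame(ratings) &&
      all(c("subject_id", "rater", "value") %in% names(ratings))) {
    wide <- ratings |>
      dplyr::select(dplyr::all_of(c("subject_id", "rater", "value"))) |>
      tidyr::pivot_wider(names_from = "rater", values_from = "value") |>
      dplyr::arrange(.data$subject_id)
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$subject_id
    return(m)
  }
  as.matrix(ratings)
}

#' @export
print.reliability_result <- function(x, ...) {
  cat("<reliability_result> ", x$model, "\n", sep = "")
  cat(sprintf("  ICC %.3f (95%% CI %.3f-%.3f), SEM %.3g (n = %d subjects)\n",
              x$icc, x$ci_low, x$ci_high, x$sem, x$n_subjects))
  invisible(x)
}
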