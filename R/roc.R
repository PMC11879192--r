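## Mann--Whitney AUC: probability that a randomly chosen case value exceeds a
## randomly chosen control value, ties counted 1/2. Computed from midranks,
## O((n1+n2) log(n1+n2)); equals literal pairwise counting exactly.
auc_mann_whitney <- function(cases, controls) {
  n1 <- length(cases)
  n0 <- length(controls)
  r <- rank(c(cases, controls), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Sensitivity/specificity over all candidate thresholds for the rule
## "positive if value >= thr" (direction = "greater") or "<= thr"
## (direction = "less"). Candidate thresholds are midpoints between adjacent
## distinct pooled values plus sentinels beyond the data range.
roc_thresholds <- function(cases, controls, direction) {
  v <- sort(unique(c(cases, controls)))
  thr <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2,
           v[length(v)] + 1)
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    if (direction == "greater") {
      sens[i] <- mean(cases >= thr[i])
      spec[i] <- mean(controls < thr[i])
    } else {
      sens[i] <- mean(cases <= thr[i])
      spec[i] <- mean(controls > thr[i])
    }
  }
  tibble::tibble(threshold = thr, sensitivity = sens, specificity = spec,
                 youden_j = sens + spec - 1)
}

#' ROC analysis with Youden-index cutoff and bootstrap CI
#'
#' Computes the ROC curve of one index for discriminating LBBB from control.
#' The area under the curve equals the Mann--Whitney probability that a
#' randomly chosen LBBB value is more extreme than a control value (ties
#' counted 1/2). The direction (which tail indicates LBBB) is chosen so that
#' AUC >= 0.5 and is recorded. The operating cutoff maximises Youden's
#' J = sensitivity + specificity - 1 over all midpoint thresholds; among
#' ties the cutoff with the highest specificity is reported. The AUC
#' confidence interval is a stratified bootstrap percentile interval
#' (subjects resampled with replacement within each group).
#'
#' @param table A data frame with `group` and the index column.
#' @param column Index column name (string).
#' @param n_boot Bootstrap replicates for the AUC CI (default 4000).
#' @param seed RNG seed for the bootstrap (default 1).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `roc_result`: list with `column`, `auc`,
#'   `ci_low`, `ci_high`, `direction` (`"greater"` if high values indicate
#'   LBBB), `youden_cutoff`, `sensitivity`, `specificity`, `thresholds`
#'   (tibble of all operating points), `degenerate` flag, `n_boot`, `seed`.
#' @export
#' @examples
#' idx <- compute_indices(generate_cohort(synth_params(20, 20, seed = 2)))
#' roc_analysis(idx, "ssi", n_boot = 200)
roc_analysis <- function(table, column, n_boot = 4000, seed = 1L,
                         conf_level = 0.95) {
  check_two_groups(table, column)
  cases <- table[[column]][table$group == "LBBB"]
  controls <- table[[column]][table$group == "control"]

  degenerate <- length(unique(c(cases, controls))) == 1L
  if (degenerate) {
    warning("all index values identical; AUC is degenerate at 0.5")
  }
  auc_raw <- auc_mann_whitney(cases, controls)
  direction <- if (auc_raw >= 0.5) "greater" else "less"
  auc <- max(auc_raw, 1 - auc_raw)

  thr <- roc_thresholds(cases, controls, direction)
  best_j <- max(thr$youden_j)
  cand <- thr[thr$youden_j >= best_j - 1e-12, , drop = FALSE]
  cand <- cand[order(-cand$specificity, cand$threshold), , drop = FALSE]
  best <- cand[1, ]

  boot <- boot_auc_replicates(
    list(a = cases), list(a = controls), n_boot = n_boot, seed = seed
  )$a
  ## report the CI for the direction-corrected AUC
  if (direction == "less") boot <- 1 - boot
  alpha <- 1 - conf_level
  ci <- unname(quantile(boot, c(alpha / 2, 1 - alpha / 2), type = 7))

  structure(
    list(column = column, auc = auc, ci_low = ci[1], ci_high = ci[2],
         direction = direction,
         youden_cutoff = best$threshold,
         sensitivity = best$sensitivity, specificity = best$specificity,
         thresholds = thr, degenerate = degenerate,
         n_boot = n_boot, seed = as.integer(seed)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> ", x$column, "\n", sep = "")
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f), direction: %s\n",
              x$auc, x$ci_low, x$ci_high,
              if (x$direction == "greater") "higher values indicate LBBB"
              else "lower values indicate LBBB"))
  cat(sprintf("  Youden cutoff %.4g: sensitivity %.3f, specificity %.3f\n",
              x$youden_cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

## Stratified bootstrap of one or more index columns measured on the SAME
## subjects: per replicate, resample case and control subjects with
## replacement (within group) once, then compute every column's AUC on that
## shared resample — this preserves the pairing needed for paired AUC
## contrasts. Returns a list of numeric vectors, one per column.
boot_auc_replicates <- function(case_cols, control_cols, n_boot, seed) {
  stopifnot(n_boot >= 1)
  n1 <- length(case_cols[[1]])
  n0 <- length(control_cols[[1]])
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  out <- lapply(case_cols, function(.) numeric(n_boot))
  for (b in seq_len(n_boot)) {
    i1 <- sample.int(n1, n1, replace = TRUE)
    i0 <- sample.int(n0, n0, replace = TRUE)
    for (nm in names(case_cols)) {
      out[[nm]][b] <- auc_mann_whitney(case_cols[[nm]][i1],
                                       control_cols[[nm]][i0])
    }
  }
  out
}

#' Compare two paired AUCs by stratified bootstrap
#'
#' Compares the discriminatory performance of two indices measured on the
#' same subjects. Per replicate, subjects are resampled with replacement
#' within each group (stratified, non-parametric); both AUCs are recomputed
#' on the same resample (paired) and their difference recorded. The
#' confidence interval is the percentile interval of the replicate
#' differences (4000 replicates by default). The two-sided bootstrap p-value
#' is `2 * min(P(delta <= 0), P(delta >= 0))` with the +1 small-sample
#' correction on numerator and denominator, capped at 1.
#'
#' Each index is compared on a fixed, caller-supplied orientation
#' (`direction_a`, `direction_b`): `"greater"` means higher values indicate
#' LBBB (AUC is the probability a case value exceeds a control value);
#' `"less"` flips the index (used e.g. for CURE, which falls with
#' dyssynchrony). The orientation is part of the index's definition, not
#' re-estimated per resample — a data-driven flip would fold the bootstrap
#' distribution at 0.5 and distort the interval precisely in the null case.
#'
#' @param table A data frame with `group` and both index columns on the same
#'   subjects (no missing values).
#' @param column_a,column_b Index column names; `delta_auc` is
#'   `AUC(column_a) - AUC(column_b)`.
#' @param n_boot Bootstrap replicates (>= 100; default 4000).
#' @param seed RNG seed (default 1).
#' @param conf_level Confidence level (default 0.95).
#' @param direction_a,direction_b `"greater"` (default) if high values of the
#'   index indicate LBBB, `"less"` if low values do.
#' @return An object of class `auc_comparison`: list with `column_a`,
#'   `column_b`, `auc_a`, `auc_b`, `delta_auc`, `ci_low`, `ci_high`,
#'   `p_value`, `n_boot`, `seed`.
#' @export
compare_auc <- function(table, column_a, column_b, n_boot = 4000, seed = 1L,
                        conf_level = 0.95,
                        direction_a = c("greater", "less"),
                        direction_b = c("greater", "less")) {
  check_two_groups(table, column_a)
  check_two_groups(table, column_b)
  if (n_boot < 100) abort("`n_boot` must be >= 100")
  direction_a <- match.arg(direction_a)
  direction_b <- match.arg(direction_b)

  is_case <- table$group == "LBBB"
  cols <- list(a = table[[column_a]], b = table[[column_b]])
  orient <- function(auc, dir) if (dir == "greater") auc else 1 - auc

  auc_a <- orient(auc_mann_whitney(cols$a[is_case], cols$a[!is_case]),
                  direction_a)
  auc_b <- orient(auc_mann_whitney(cols$b[is_case], cols$b[!is_case]),
                  direction_b)

  reps <- boot_auc_replicates(
    lapply(cols, function(v) v[is_case]),
    lapply(cols, function(v) v[!is_case]),
    n_boot = n_boot, seed = seed
  )
  delta <- orient(reps$a, direction_a) - orient(reps$b, direction_b)
  alpha <- 1 - conf_level
  ci <- unname(quantile(delta, c(alpha / 2, 1 - alpha / 2), type = 7))
  p <- min(1, 2 * min((sum(delta <= 0) + 1) / (n_boot + 1),
                      (sum(delta >= 0) + 1) / (n_boot + 1)))

  structure(
    list(column_a = column_a, column_b = column_b,
         auc_a = auc_a, auc_b = auc_b, delta_auc = auc_a - auc_b,
         ci_low = ci[1], ci_high = ci[2], p_value = p,
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "auc_comparison"
  )
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat("<auc_comparison> ", x$column_a, " vs ", x$column_b, "\n", sep = "")
  cat(sprintf("  AUC %.3f vs %.3f; delta %.3f (95%% CI %.3f-%.3f), p = %s\n",
              x$auc_a, x$auc_b, x$delta_auc, x$ci_low, x$ci_high,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}
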