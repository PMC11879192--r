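test_that("group_compare: rank-sum statistic, medians and IQRs", {
  tb <- make_table(lbbb = c(4, 5, 6), control = c(1, 2, 3))
  gc <- group_compare(tb, "ssi")
  expect_equal(gc$statistic, 9)           # all 9 pairs favour LBBB
  expect_lt(gc$p_value, 0.11)             # exact two-sided p = 0.1
  expect_equal(gc$p_value, 0.1, tolerance = 1e-12)

  ## median/IQR with linear interpolation between order statistics
  tb2 <- make_table(lbbb = c(1, 2, 3, 4), control = c(1, 2, 3, 4))
  gc2 <- group_compare(tb2, "ssi")
  expect_equal(gc2$summary$median, c(2.5, 2.5))
  expect_equal(gc2$summary$q25, c(1.75, 1.75))
  expect_equal(gc2$summary$q75, c(3.25, 3.25))
  ## identical value multisets: exact test would give p = 1, but ties force
  ## the normal approximation; either way no evidence of a difference
  expect_gt(gc2$p_value, 0.9)

  expect_error(group_compare(make_table(1, c(2, 3)), "ssi"), "2 subjects")
  expect_error(group_compare(tb, "nope"), "not found")
})

test_that("identical untied samples give p = 1 under the exact rank test", {
  tb <- make_table(lbbb = c(1.5, 3.5, 5.5), control = c(1, 3, 6))
  gc <- group_compare(tb, "ssi")
  expect_match(gc$method, "exact")
  expect_gt(gc$p_value, 0.6)
})

test_that("spearman_corr reproduces hand-ranked values and flags constants", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(1:10, -(1:10)^3)$rho, -1)
  expect_equal(spearman_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  expect_error(spearman_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_corr(1:3, 1:4), "equal length")
})

test_that("logistic_or matches an independent Newton oracle and unit algebra", {
  ## predictor independent of outcome: OR = 1
  tb0 <- tibble::tibble(group = c("control", "LBBB", "control", "LBBB"),
                        x = c(0, 0, 1, 1))
  expect_equal(logistic_or(tb0, "x")$or, 1, tolerance = 1e-8)

  ## fixed printed 8-row toy table vs brute-force IRLS
  x <- c(0.5, 1.2, 2.3, 2.9, 3.4, 4.1, 5.0, 5.6)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  tb <- tibble::tibble(group = ifelse(y == 1, "LBBB", "control"), idx = x)
  fit <- logistic_or(tb, "idx")
  or <- oracle_logistic(x, y)
  expect_equal(fit$or, exp(or$beta), tolerance = 1e-6)
  expect_equal(fit$ci_low, unname(exp(or$beta - qnorm(0.975) * or$se)),
               tolerance = 1e-4)

  ## reporting-unit algebra: OR per -0.10 equals OR per unit to the -0.10
  fit_neg <- logistic_or(tb, "idx", unit = -0.10)
  expect_equal(fit_neg$or, fit$or^(-0.10), tolerance = 1e-12)
  expect_lte(fit_neg$ci_low, fit_neg$ci_high)

  ## perfect separation is an explicit error, not a huge OR
  sep <- tibble::tibble(group = rep(c("control", "LBBB"), each = 4),
                        idx = c(1:4, 6:9))
  expect_error(logistic_or(sep, "idx"), "separation")
})

test_that("roc_analysis: AUC, direction, Youden point, degenerate input", {
  ## perfectly separated groups
  tb <- make_table(lbbb = c(5, 6, 7), control = c(1, 2, 3))
  r <- roc_analysis(tb, "ssi", n_boot = 200, seed = 1)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_identical(r$direction, "greater")

  ## ties counted one half: controls {1,2,3}, cases {2,3,4} -> 7/9
  tb2 <- make_table(lbbb = c(2, 3, 4), control = c(1, 2, 3))
  r2 <- roc_analysis(tb2, "ssi", n_boot = 200, seed = 1)
  expect_equal(r2$auc, 7 / 9, tolerance = 1e-12)

  ## a protective index flips direction
  tb3 <- make_table(lbbb = c(0.5, 0.6), control = c(0.8, 0.9), col = "cure")
  r3 <- roc_analysis(tb3, "cure", n_boot = 200, seed = 1)
  expect_identical(r3$direction, "less")
  expect_equal(r3$auc, 1)

  ## all-identical values: degenerate AUC 0.5 with a warning
  tb4 <- make_table(lbbb = c(2, 2), control = c(2, 2, 2))
  expect_warning(r4 <- roc_analysis(tb4, "ssi", n_boot = 150, seed = 1),
                 "degenerate")
  expect_equal(r4$auc, 0.5)
})

test_that("AUC and Youden cutoff equal brute-force oracles on random tables", {
  set.seed(60)
  for (i in 1:200) {
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    cases <- round(rnorm(n1, 1), 1)        # rounding induces ties
    controls <- round(rnorm(n0), 1)
    tb <- make_table(cases, controls)
    r <- roc_analysis(tb, "ssi", n_boot = 100, seed = 1)
    a_or <- oracle_auc(cases, controls)
    expect_equal(max(a_or, 1 - a_or), r$auc, tolerance = 1e-12)
    yo <- oracle_youden(cases, controls, r$direction)
    expect_equal(r$sensitivity + r$specificity - 1, yo$j, tolerance = 1e-12)
    expect_equal(r$specificity, yo$spec, tolerance = 1e-12)
  }
})

test_that("compare_auc: self-comparison collapses to zero; separation detected", {
  set.seed(61)
  tb <- make_table(rnorm(15, 1), rnorm(15))
  tb$ssi2 <- tb$ssi
  cmp <- compare_auc(tb, "ssi", "ssi2", n_boot = 300, seed = 5)
  expect_identical(cmp$delta_auc, 0)
  expect_identical(c(cmp$ci_low, cmp$ci_high), c(0, 0))
  expect_equal(cmp$p_value, 1)

  ## strong index vs pure noise at n = 40/group: CI excludes zero
  set.seed(62)
  tb2 <- make_table(rnorm(40, 4), rnorm(40))
  tb2$noise <- rnorm(80)
  cmp2 <- compare_auc(tb2, "ssi", "noise", n_boot = 400, seed = 6)
  expect_gt(cmp2$ci_low, 0)
  expect_lt(cmp2$p_value, 0.01)
  expect_error(compare_auc(tb2, "ssi", "noise", n_boot = 50), "n_boot")
})

test_that("compare_auc is deterministic given its seed", {
  set.seed(63)
  tb <- make_table(rnorm(12, 1), rnorm(12))
  tb$alt <- tb$ssi + rnorm(24, 0, 0.5)
  c1 <- compare_auc(tb, "ssi", "alt", n_boot = 250, seed = 11)
  c2 <- compare_auc(tb, "ssi", "alt", n_boot = 250, seed = 11)
  expect_identical(tidy(c1), tidy(c2))
})

test_that("icc_single matches the ANOVA oracle and model orderings", {
  set.seed(70)
  ## random matrices vs literal mean-squares oracle
  for (i in 1:25) {
    m <- matrix(rnorm(20, 10, 3), ncol = 2) + rnorm(10, 0, 2)
    r2 <- icc_single(m, "two_way_random_absolute_single")
    r3 <- icc_single(m, "two_way_fixed_single")
    or <- oracle_icc(m)
    expect_equal(r2$icc, or$icc2, tolerance = 1e-10)
    expect_equal(r3$icc, or$icc3, tolerance = 1e-10)
    expect_equal(r2$sem, or$sem, tolerance = 1e-10)
    expect_true(r2$ci_low <= r2$icc && r2$icc <= r2$ci_high)
    expect_true(r3$ci_low <= r3$icc && r3$icc <= r3$ci_high)
  }

  ## duplicated rater: perfect agreement
  truth <- rnorm(10, 5, 2)
  dup <- cbind(truth, truth)
  rd <- icc_single(dup)
  expect_identical(rd$icc, 1)
  expect_identical(rd$sem, 0)

  ## constant offset: consistency (3,1) forgives it, absolute (2,1) does not
  off <- cbind(truth, truth + 1.5)
  expect_gt(icc_single(off, "two_way_fixed_single")$icc,
            icc_single(off, "two_way_random_absolute_single")$icc)

  ## long-format input is pivoted
  long <- tibble::tibble(
    subject_id = rep(sprintf("P%02d", 1:10), each = 2),
    rater = rep(c("r1", "r2"), 10),
    value = as.vector(t(off))
  )
  expect_equal(icc_single(long, "two_way_fixed_single")$icc,
               icc_single(off, "two_way_fixed_single")$icc)

  ## degenerate and contract errors
  expect_error(icc_single(cbind(rep(1, 6), rep(1, 6))), "between-subject")
  expect_error(icc_single(matrix(rnorm(8), ncol = 2)), "at least 5")
  expect_error(icc_single(matrix(rnorm(30), ncol = 3)), "exactly 2")
})
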