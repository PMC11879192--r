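test_that("spatial Fourier terms match hand-computed DFT values", {
  ## all segments constant -10%: |sum|^2 = (6*10)^2 = 3600, no first harmonic
  m <- matrix(-10, 6, 4, dimnames = list(segment_names, NULL))
  ft <- spatial_fourier_terms(m)
  expect_equal(ft$s0, rep(3600, 4), tolerance = 1e-12)
  expect_equal(ft$s1, rep(0, 4), tolerance = 1e-12)

  ## pure first spatial harmonic cos(2*pi*k/6): X1 = 3, so S1 = 9, S0 = 0
  k <- 0:5
  m1 <- matrix(cos(2 * pi * k / 6), 6, 1, dimnames = list(segment_names, NULL))
  ft1 <- spatial_fourier_terms(m1)
  expect_equal(ft1$s0, 0, tolerance = 1e-12)
  expect_equal(ft1$s1, 9, tolerance = 1e-12)

  ## magnitude convention is the square root of the power convention
  ftm <- spatial_fourier_terms(m1, power = "magnitude")
  expect_equal(ftm$s1, 3, tolerance = 1e-12)
})

test_that("Fourier terms equal the literal-summation oracle on random input", {
  set.seed(20)
  for (i in 1:200) {
    m <- matrix(rnorm(6 * 7, -10, 6), 6, 7, dimnames = list(segment_names, NULL))
    ft <- spatial_fourier_terms(m)
    or <- oracle_fourier_terms(m)
    expect_lt(max(abs(ft$s0 - or$s0)), 1e-12 * max(1, max(abs(or$s0))))
    expect_lt(max(abs(ft$s1 - or$s1)), 1e-12 * max(1, max(abs(or$s1))))
  }
})

test_that("CURE attains its analytic limits and the worked cosine value", {
  ## spatially uniform strain, arbitrary waveform -> CURE = 1
  w <- c(0, -4, -9, -15, -12, -6)
  mu <- matrix(rep(w, each = 6), 6, 6, dimnames = list(segment_names, NULL))
  expect_identical(compute_cure(mu), 1)

  ## pure first-harmonic spatial pattern at every frame -> CURE = 0
  k <- 0:5
  a <- c(-2, -5, -8, -6, -3)
  mh <- outer(cos(2 * pi * k / 6), a)
  rownames(mh) <- segment_names
  expect_equal(compute_cure(mh), 0, tolerance = 1e-12)

  ## -10 + 2*cos(2*pi*k/6): S0 = 3600, S1 = 36 -> CURE = 3600/3636
  mc <- matrix(rep(-10 + 2 * cos(2 * pi * k / 6), 5), 6, 5,
               dimnames = list(segment_names, NULL))
  expect_equal(compute_cure(mc), 3600 / 3636, tolerance = 1e-12)
  expect_equal(oracle_cure(mc), 3600 / 3636, tolerance = 1e-12)

  ## all-zero frames (e.g. the ED frame) count as perfectly synchronous
  mz <- cbind(0, mh[, 1])
  rownames(mz) <- segment_names
  expect_equal(compute_cure(mz), 0.5, tolerance = 1e-12)
})

test_that("CURE equals the brute-force oracle and respects its invariances", {
  set.seed(21)
  for (i in 1:200) {
    m <- random_strain_matrix(n_frames = 9)
    cure <- compute_cure(m)
    expect_lt(abs(cure - oracle_cure(m)), 1e-12)
    expect_gte(cure, 0)
    expect_lte(cure, 1)
  }
  ## scale invariance and rotation invariance (DFT magnitude property)
  set.seed(22)
  for (i in 1:50) {
    m <- random_strain_matrix(n_frames = 8)
    expect_equal(compute_cure(m * 3.7), compute_cure(m), tolerance = 1e-12)
    expect_equal(compute_cure(m * -0.4), compute_cure(m), tolerance = 1e-12)
    rot <- unname(m[c(3:6, 1:2), ])    # circular rotation of segment order
    expect_equal(compute_cure(rot), compute_cure(m), tolerance = 1e-12)
  }
  ## pooled variant also stays in [0, 1] and matches its oracle
  set.seed(23)
  m <- random_strain_matrix(10)
  expect_equal(compute_cure(m, pooling = "pooled"),
               oracle_cure(m, pooling = "pooled"), tolerance = 1e-12)
})

test_that("stretch_sum follows its windowed positive-increment definition", {
  s <- c(0, -2, -1, -3, -2.5)
  expect_equal(stretch_sum(s, 0, 4, require_prior_shortening = TRUE), 1.5)
  expect_equal(stretch_sum(s, 0, 4, require_prior_shortening = FALSE), 1.5)
  ## stretch preceding any shortening does not count
  expect_equal(stretch_sum(c(0, 1, 2), 0, 2, require_prior_shortening = TRUE), 0)
  expect_equal(stretch_sum(c(0, 1, 2), 0, 2, require_prior_shortening = FALSE), 2)
  ## monotone decreasing series
  expect_equal(stretch_sum(c(0, -1, -5, -9), 0, 3, TRUE), 0)
  expect_equal(stretch_sum(c(0, -1, -5, -9), 0, 3, FALSE), 0)
  ## degenerate single-frame window and inverted window
  expect_equal(stretch_sum(s, 2, 2, FALSE), 0)
  expect_error(stretch_sum(s, 3, 1, FALSE), "window")
  expect_error(stretch_sum(s, 0, 7, FALSE), "within")
})

test_that("SPS and SRS reproduce the hand-worked subject", {
  cu <- subject_curves(worked_subject(), "S1")
  sps <- compute_sps(cu)
  expect_equal(sps$sps_antlat, 3.0)
  expect_equal(sps$sps_inflat, 1.0)
  expect_equal(sps$sps, 2.0)
  srs <- compute_srs(cu)
  expect_equal(srs$srs_antsept, 1.5)
  expect_equal(srs$srs_infsept, 0.5)
  expect_equal(srs$srs, 1.0)
  res <- compute_ssi(cu)
  expect_equal(res$ssi, 3.0)
  expect_equal(res$ssi, res$sps + res$srs, tolerance = 1e-12)
  expect_equal(res$ssi,
               (res$sps_antlat + res$sps_inflat) / 2 +
                 (res$srs_antsept + res$srs_infsept) / 2,
               tolerance = 1e-12)
})

test_that("SPS/SRS match the enumeration oracle exactly on random subjects", {
  set.seed(24)
  for (i in 1:200) {
    n <- sample(8:14, 1)
    m <- random_strain_matrix(n)
    avo <- sample.int(n - 4, 1)
    avc <- avo + sample.int(n - 2 - avo, 1)
    cu <- list(strain = m, ed_frame = 0L, avo_frame = avo, avc_frame = avc)
    sps <- compute_sps(cu)
    expect_identical(sps$sps_antlat,
                     oracle_stretch(m["anterolateral", ], 0, avo, FALSE))
    expect_identical(sps$sps_inflat,
                     oracle_stretch(m["inferolateral", ], 0, avo, FALSE))
    srs <- compute_srs(cu)
    expect_identical(srs$srs_antsept,
                     oracle_stretch(m["anteroseptal", ], 0, avc, TRUE))
    expect_identical(srs$srs_infsept,
                     oracle_stretch(m["inferoseptal", ], 0, avc, TRUE))
  }
})

test_that("SSI is non-negative and positively homogeneous; CURE scale-free", {
  set.seed(25)
  for (i in 1:50) {
    n <- 12
    m <- random_strain_matrix(n)
    cu <- list(strain = m, ed_frame = 0L, avo_frame = 3L, avc_frame = 8L)
    r1 <- compute_ssi(cu)
    expect_gte(r1$ssi, 0)
    c_scale <- runif(1, 0.2, 5)
    cu2 <- cu; cu2$strain <- m * c_scale
    r2 <- compute_ssi(cu2)
    expect_equal(r2$ssi, c_scale * r1$ssi, tolerance = 1e-12)
    expect_equal(r2$cure, r1$cure, tolerance = 1e-12)
  }
})

test_that("a synchronous monotone-shortening subject has SSI 0 and CURE 1", {
  w <- c(0, -3, -7, -12, -15, -13, -8, -3)
  m <- matrix(rep(w, each = 6), 6, length(w),
              dimnames = list(segment_names, NULL))
  cu <- list(strain = m, ed_frame = 0L, avo_frame = 2L, avc_frame = 4L)
  res <- compute_ssi(cu)
  expect_identical(res$ssi, 0)
  expect_identical(res$cure, 1)
})

test_that("compute_indices maps subjects and records conventions", {
  co <- generate_cohort(synth_params(n_lbbb = 3, n_control = 2, seed = 31))
  idx <- compute_indices(co)
  expect_identical(nrow(idx), 5L)
  expect_setequal(
    names(idx),
    c("subject_id", "group", "cure", "sps_antlat", "sps_inflat",
      "srs_antsept", "srs_infsept", "sps", "srs", "ssi")
  )
  expect_identical(attr(idx, "conventions")$fourier_power, "power")
  ## per-subject agreement with the single-subject entry point
  cu <- subject_curves(co, idx$subject_id[1])
  expect_equal(idx$ssi[1], compute_ssi(cu)$ssi)
  ## wrong segment count is a contract error
  expect_error(spatial_fourier_terms(matrix(0, 5, 4)), "6 segment")
})
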