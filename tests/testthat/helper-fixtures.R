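## Fixture builders: small cohorts constructed in code.

segment_names <- dyssync::aha_segments()

## One-subject cohort from a 6 x n strain matrix (rows in canonical order).
make_subject_cohort <- function(mat, ed = 0L, avo, avc, group = "LBBB",
                                id = "S1", validate = TRUE) {
  n <- ncol(mat)
  strain <- tibble::tibble(
    subject_id = id, group = group,
    segment = rep(segment_names, each = n),
    frame = rep(0:(n - 1), times = 6),
    strain_pct = as.vector(t(mat))
  )
  events <- tibble::tibble(subject_id = id, ed_frame = as.integer(ed),
                           avo_frame = as.integer(avo),
                           avc_frame = as.integer(avc))
  dyssync::strain_cohort(strain, events, provenance = "test fixture",
                         validate = validate)
}

## Random valid 6 x n strain matrix: zero at frame 0, bounded values.
random_strain_matrix <- function(n_frames = 12) {
  m <- matrix(stats::rnorm(6 * n_frames, -8, 5), nrow = 6,
              dimnames = list(segment_names, NULL))
  m - m[, 1]
}

## Random small cohort for round-trip tests.
random_cohort <- function(n_subjects = 3, n_frames = 10) {
  mats <- lapply(seq_len(n_subjects), function(i) random_strain_matrix(n_frames))
  strain <- purrr::imap_dfr(mats, function(m, i) {
    tibble::tibble(
      subject_id = sprintf("S%02d", i),
      group = if (i %% 2 == 0) "control" else "LBBB",
      segment = rep(segment_names, each = n_frames),
      frame = rep(0:(n_frames - 1), times = 6),
      strain_pct = as.vector(t(m))
    )
  })
  events <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    ed_frame = 0L,
    avo_frame = 2L,
    avc_frame = as.integer(n_frames - 2L)
  )
  dyssync::strain_cohort(strain, events, provenance = "random test cohort")
}

## The hand-worked subject from the index definitions: n = 6 frames,
## ed = 0, avo = 3, avc = 4. Lateral rows give SPS (3.0, 1.0), septal rows
## give SRS (1.5, 0.5); SSI = 2.0 + 1.0 = 3.0.
worked_subject <- function() {
  m <- rbind(
    anteroseptal  = c(0, -2.0, -1.0, -3.0, -2.5, -2.0),
    anterior      = c(0, -1.0, -2.0, -3.0, -3.5, -3.0),
    anterolateral = c(0,  1.5,  0.5,  2.0,  1.0,  0.0),
    inferolateral = c(0,  1.0,  1.0,  1.0,  0.0, -1.0),
    inferior      = c(0, -1.0, -2.0, -3.0, -3.0, -2.0),
    inferoseptal  = c(0, -3.0, -2.5, -4.0, -4.0, -3.5)
  )
  make_subject_cohort(m, ed = 0, avo = 3, avc = 4)
}

## Two-group index table for the statistics modules.
make_table <- function(lbbb, control, col = "ssi") {
  tb <- tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(length(lbbb) + length(control))),
    group = rep(c("LBBB", "control"), c(length(lbbb), length(control))),
    value = c(lbbb, control)
  )
  names(tb)[names(tb) == "value"] <- col
  tb
}
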