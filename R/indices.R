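#' Spatial Fourier terms of segmental strain
#'
#' For every timeframe, computes the discrete Fourier transform of the six
#' circumferentially ordered segment strains and returns the zero-order and
#' first-order terms. With `power = "power"` (the default) the terms are the
#' squared magnitudes of the DFT coefficients, `S0(t) = |X0(t)|^2` and
#' `S1(t) = |X1(t)|^2`; with `"magnitude"` they are plain magnitudes. The
#' first-order term is one-sided (order +1 only); for real strain this differs
#' from the two-sided convention by a constant factor on S1 and so changes
#' CURE's numeric value but not its ordering across subjects.
#'
#' @param strain A 6 x n numeric matrix of strain in percent, rows in the
#'   canonical circumferential segment order (see [aha_segments()]), or a
#'   list as returned by [subject_curves()].
#' @param power `"power"` (squared magnitude, default) or `"magnitude"`.
#' @return A tibble with columns `frame` (0-based), `s0` and `s1`
#'   (non-negative reals).
#' @export
#' @examples
#' m <- matrix(-10, nrow = 6, ncol = 4, dimnames = list(aha_segments(), NULL))
#' spatial_fourier_terms(m) # s0 = 3600, s1 = 0 at every frame
spatial_fourier_terms <- function(strain, power = c("power", "magnitude")) {
  power <- match.arg(power)
  strain <- as_strain_matrix(strain)
  n <- ncol(strain)
  k <- 0:5
  w0 <- exp(-2i * pi * 0 * k / 6)  # all ones; kept for symmetry with w1
  w1 <- exp(-2i * pi * 1 * k / 6)
  x0 <- drop(t(strain) %*% w0)     # per-frame order-0 DFT coefficient
  x1 <- drop(t(strain) %*% w1)
  s0 <- Mod(x0)
  s1 <- Mod(x1)
  if (power == "power") {
    s0 <- s0^2
    s1 <- s1^2
  }
  tibble::tibble(frame = seq_len(n) - 1L, s0 = s0, s1 = s1)
}

as_strain_matrix <- function(strain) {
  if (is.list(strain) && !is.null(strain$strain)) strain <- strain$strain
  if (!is.matrix(strain) || !is.numeric(strain)) {
    abort("`strain` must be a numeric segment-by-frame matrix")
  }
  if (nrow(strain) != 6L) {
    abort(paste0("strain matrix must have exactly 6 segment rows, got ",
                 nrow(strain)))
  }
  if (!is.null(rownames(strain))) {
    if (!setequal(rownames(strain), SEGMENTS)) {
      abort("strain matrix row names must be the 6 AHA segments")
    }
    strain <- strain[SEGMENTS, , drop = FALSE]
  }
  strain
}

#' Circumferential uniformity ratio estimate (CURE)
#'
#' CURE summarises the spatial uniformity of circumferential strain over the
#' cardiac cycle. Per timeframe, strain across the six circumferentially
#' ordered segments is Fourier transformed; the zero-order power `S0(t)`
#' captures spatially uniform deformation and the first-order power `S1(t)`
#' captures a single-cycle spatial pattern (e.g. septum stretching while the
#' lateral wall shortens). CURE averages the uniform fraction over the `n`
#' timeframes:
#' \deqn{\mathrm{CURE} = \frac{1}{n}\sum_{t=1}^{n}
#'   \frac{S_0(t)}{S_0(t) + S_1(t)}}
#' and ranges from 0 (perfect dyssynchrony: pure first-harmonic spatial
#' pattern) to 1 (perfect synchrony: spatially uniform strain). A timeframe
#' with `S0(t) + S1(t) = 0` (all-zero strain, e.g. the end-diastolic reference
#' frame itself) is spatially uniform and contributes 1 to the average.
#'
#' `pooling = "pooled"` instead computes `sum(S0) / sum(S0 + S1)` over all
#' timeframes; the per-frame average is the default reading.
#'
#' @inheritParams spatial_fourier_terms
#' @param pooling `"per_frame"` (default) or `"pooled"`.
#' @return CURE, a single number in \[0, 1\].
#' @export
compute_cure <- function(strain, power = c("power", "magnitude"),
                         pooling = c("per_frame", "pooled")) {
  pooling <- match.arg(pooling)
  terms <- spatial_fourier_terms(strain, power = power)
  tot <- terms$s0 + terms$s1
  if (pooling == "per_frame") {
    ratio <- ifelse(tot == 0, 1, terms$s0 / tot)
    mean(ratio)
  } else {
    if (sum(tot) == 0) 1 else sum(terms$s0) / sum(tot)
  }
}

#' Cumulative stretch within a frame window
#'
#' Sums the positive consecutive-frame strain increments
#' `max(0, strain[i+1] - strain[i])` over the frame window
#' `[window_start, window_end]` (0-based, inclusive endpoints). With
#' `require_prior_shortening = TRUE`, increments only count at transitions
#' occurring strictly after the first transition with a negative increment
#' inside the window — the operational reading of stretch "following early
#' systolic shortening". No sub-frame interpolation is applied; the sum is
#' 0 when the window holds no qualifying stretch.
#'
#' @param strain_series Numeric vector of one segment's strain in percent,
#'   element `i` being frame `i - 1`.
#' @param window_start,window_end 0-based inclusive frame window.
#' @param require_prior_shortening Count stretch only after shortening has
#'   begun within the window.
#' @return Non-negative cumulative stretch in percent.
#' @export
#' @examples
#' stretch_sum(c(0, -2, -1, -3, -2.5), 0, 4, require_prior_shortening = TRUE)
stretch_sum <- function(strain_series, window_start, window_end,
                        require_prior_shortening = FALSE) {
  n <- length(strain_series)
  if (window_start > window_end) {
    abort("`window_start` must be <= `window_end`")
  }
  if (window_start < 0 || window_end > n - 1L) {
    abort("stretch window must lie within the strain series")
  }
  idx <- seq(window_start + 1L, window_end + 1L) # to 1-based
  if (length(idx) < 2L) return(0)
  inc <- diff(strain_series[idx])
  if (require_prior_shortening) {
    first_short <- which(inc < 0)[1]
    if (is.na(first_short)) return(0)
    inc <- inc[seq_along(inc) > first_short]
  }
  sum(pmax(0, inc))
}

#' Lateral-wall systolic pre-stretch (SPS)
#'
#' Cumulative stretch of the anterolateral and inferolateral segments between
#' the end-diastolic reference frame and aortic valve opening — lateral-wall
#' lengthening before ejection, the mechanical counterpart of early unopposed
#' septal contraction in LBBB.
#'
#' @param curves A list as returned by [subject_curves()] (fields `strain`,
#'   `ed_frame`, `avo_frame`, `avc_frame`), or a 6 x n strain matrix with the
#'   event frames given explicitly.
#' @param ed_frame,avo_frame,avc_frame 0-based event frames (only needed when
#'   `curves` is a bare matrix).
#' @return A tibble with columns `sps_antlat`, `sps_inflat`, `sps` (their
#'   arithmetic mean), all non-negative, in percent.
#' @export
compute_sps <- function(curves, ed_frame = NULL, avo_frame = NULL,
                        avc_frame = NULL) {
  cu <- as_subject(curves, ed_frame, avo_frame, avc_frame)
  per <- vapply(LATERAL_SEGMENTS, function(seg) {
    stretch_sum(cu$strain[seg, ], cu$ed_frame, cu$avo_frame,
                require_prior_shortening = FALSE)
  }, numeric(1))
  tibble::tibble(
    sps_antlat = per[["anterolateral"]],
    sps_inflat = per[["inferolateral"]],
    sps = mean(per)
  )
}

#' Septal rebound stretch (SRS)
#'
#' Cumulative stretch of the anteroseptal and inferoseptal segments occurring
#' after early systolic shortening and before aortic valve closure — the
#' septal re-lengthening during ejection that follows the septum's early
#' unopposed contraction in LBBB. Within each segment the window runs from
#' the end-diastolic reference frame to aortic valve closure and stretch only
#' counts after the first negative consecutive-frame increment.
#'
#' @inheritParams compute_sps
#' @return A tibble with columns `srs_antsept`, `srs_infsept`, `srs` (their
#'   arithmetic mean), all non-negative, in percent.
#' @export
compute_srs <- function(curves, ed_frame = NULL, avo_frame = NULL,
                        avc_frame = NULL) {
  cu <- as_subject(curves, ed_frame, avo_frame, avc_frame)
  per <- vapply(SEPTAL_SEGMENTS, function(seg) {
    stretch_sum(cu$strain[seg, ], cu$ed_frame, cu$avc_frame,
                require_prior_shortening = TRUE)
  }, numeric(1))
  tibble::tibble(
    srs_antsept = per[["anteroseptal"]],
    srs_infsept = per[["inferoseptal"]],
    srs = mean(per)
  )
}

#' Systolic stretch index (SSI) and full dyssynchrony result for one subject
#'
#' SSI is the sum of lateral-wall systolic pre-stretch and septal rebound
#' stretch,
#' \deqn{\mathrm{SSI} = \frac{\mathrm{SPS}_{antlat} + \mathrm{SPS}_{inflat}}{2}
#'   + \frac{\mathrm{SRS}_{antsept} + \mathrm{SRS}_{infsept}}{2},}
#' in strain percent units. The returned row also carries CURE so one call
#' yields the full per-subject dyssynchrony result.
#'
#' @inheritParams compute_sps
#' @inheritParams compute_cure
#' @return A one-row tibble with columns `cure`, `sps_antlat`, `sps_inflat`,
#'   `srs_antsept`, `srs_infsept`, `sps`, `srs`, `ssi`.
#' @export
compute_ssi <- function(curves, ed_frame = NULL, avo_frame = NULL,
                        avc_frame = NULL,
                        power = c("power", "magnitude"),
                        pooling = c("per_frame", "pooled")) {
  cu <- as_subject(curves, ed_frame, avo_frame, avc_frame)
  sps_tbl <- compute_sps(cu)
  srs_tbl <- compute_srs(cu)
  tibble::tibble(
    cure = compute_cure(cu$strain, power = power, pooling = pooling),
    sps_antlat = sps_tbl$sps_antlat, sps_inflat = sps_tbl$sps_inflat,
    srs_antsept = srs_tbl$srs_antsept, srs_infsept = srs_tbl$srs_infsept,
    sps = sps_tbl$sps, srs = srs_tbl$srs,
    ssi = sps_tbl$sps + srs_tbl$srs
  )
}

as_subject <- function(curves, ed_frame, avo_frame, avc_frame) {
  if (is.matrix(curves)) {
    if (is.null(ed_frame) || is.null(avo_frame) || is.null(avc_frame)) {
      abort("event frames are required when `curves` is a bare matrix")
    }
    curves <- list(strain = curves, ed_frame = ed_frame,
                   avo_frame = avo_frame, avc_frame = avc_frame)
  }
  curves$strain <- as_strain_matrix(curves$strain)
  n <- ncol(curves$strain)
  with(curves, {
    if (!(0 <= ed_frame && ed_frame <= avo_frame && avo_frame < avc_frame &&
          avc_frame < n)) {
      abort("event frames must satisfy 0 <= ed <= avo < avc < n_frames")
    }
  })
  curves
}

#' Per-subject dyssynchrony indices for a cohort
#'
#' Computes CURE, SPS, SRS and SSI for every subject and returns a tidy
#' per-subject table — the input to the statistical pipeline
#' ([group_compare()], [roc_analysis()], [compare_auc()],
#' [logistic_or()], [run_full_analysis()]).
#'
#' @param cohort A [strain_cohort()].
#' @param power,pooling CURE conventions, see [compute_cure()].
#' @return A tibble with one row per subject: `subject_id`, `group`, `cure`,
#'   `sps_antlat`, `sps_inflat`, `srs_antsept`, `srs_infsept`, `sps`, `srs`,
#'   `ssi`. Convention choices are recorded in the `"conventions"` attribute.
#' @export
#' @examples
#' cohort <- generate_cohort(synth_params(n_lbbb = 3, n_control = 3, seed = 1))
#' compute_indices(cohort)
compute_indices <- function(cohort, power = c("power", "magnitude"),
                            pooling = c("per_frame", "pooled")) {
  power <- match.arg(power)
  pooling <- match.arg(pooling)
  stopifnot(inherits(cohort, "strain_cohort"))
  subj <- cohort_subject_list(cohort)
  out <- purrr::imap_dfr(subj, function(cu, id) {
    dplyr::bind_cols(
      tibble::tibble(subject_id = id, group = cu$group),
      compute_ssi(cu, power = power, pooling = pooling)
    )
  })
  attr(out, "conventions") <- list(fourier_power = power,
                                   cure_pooling = pooling,
                                   first_order_term = "one_sided")
  out
}
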