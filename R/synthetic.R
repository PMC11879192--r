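#' Parameters for the synthetic strain-cohort generator
#'
#' The generator emulates the mechanical signatures that distinguish left
#' bundle branch block (LBBB) from normal activation in mid-ventricular
#' circumferential strain: in LBBB, early unopposed septal shortening is
#' followed by septal rebound stretch during ejection, while the lateral wall
#' is pre-stretched before aortic valve opening and shortens late. Controls
#' shorten smoothly and near-uniformly to a peak around aortic valve closure
#' and relax back towards the end-diastolic reference.
#'
#' Defaults describe a plausible mid-ventricular slice at clinical CMR cine
#' temporal resolution: 24 frames per cardiac cycle, mean peak segmental
#' shortening of -15% (between-segment/subject SD 2%), aortic valve opening
#' and closure at 15% and 45% of the cycle, septal rebound amplitude 6%,
#' lateral pre-stretch 4%, lateral shortening delayed by 12% of the cycle,
#' and 0.5% additive frame noise.
#'
#' @param n_lbbb,n_control Subjects per arm (defaults 44 and 36).
#' @param n_frames Timeframes covering the cardiac cycle (>= 8; default 24).
#' @param peak_strain_pct Mean peak segmental strain in percent (negative;
#'   default -15).
#' @param peak_strain_sd SD of per-subject-and-segment peak strain (default 2).
#' @param avo_frac,avc_frac Aortic valve opening/closure as fractions of the
#'   cycle (defaults 0.15 and 0.45; must satisfy 0 < avo < avc < 1).
#' @param lbbb_rebound_amp_pct Septal rebound stretch amplitude in percent
#'   (default 6).
#' @param lbbb_prestretch_amp_pct Lateral pre-ejection stretch amplitude in
#'   percent (default 4).
#' @param lbbb_lateral_delay_frac Delay of lateral-wall peak shortening as a
#'   fraction of the cycle (default 0.12).
#' @param noise_sd_pct SD of additive per-frame Gaussian measurement noise in
#'   percent (default 0.5).
#' @param seed RNG seed for [generate_cohort()].
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_lbbb = 44, n_control = 36, n_frames = 24,
                         peak_strain_pct = -15, peak_strain_sd = 2,
                         avo_frac = 0.15, avc_frac = 0.45,
                         lbbb_rebound_amp_pct = 6,
                         lbbb_prestretch_amp_pct = 4,
                         lbbb_lateral_delay_frac = 0.12,
                         noise_sd_pct = 0.5, seed = 1L) {
  p <- list(
    n_lbbb = as.integer(n_lbbb), n_control = as.integer(n_control),
    n_frames = as.integer(n_frames),
    peak_strain_pct = peak_strain_pct, peak_strain_sd = peak_strain_sd,
    avo_frac = avo_frac, avc_frac = avc_frac,
    lbbb_rebound_amp_pct = lbbb_rebound_amp_pct,
    lbbb_prestretch_amp_pct = lbbb_prestretch_amp_pct,
    lbbb_lateral_delay_frac = lbbb_lateral_delay_frac,
    noise_sd_pct = noise_sd_pct, seed = as.integer(seed)
  )
  if (p$n_lbbb < 1 || p$n_control < 1) abort("group sizes must be >= 1")
  if (p$n_frames < 8) abort("`n_frames` must be >= 8")
  if (!(p$peak_strain_pct < 0)) abort("`peak_strain_pct` must be negative")
  if (p$peak_strain_sd < 0 || p$noise_sd_pct < 0 ||
      p$lbbb_rebound_amp_pct < 0 || p$lbbb_prestretch_amp_pct < 0 ||
      p$lbbb_lateral_delay_frac < 0) {
    abort("amplitudes, delays and noise/jitter SDs must be >= 0")
  }
  if (!(0 < p$avo_frac && p$avo_frac < p$avc_frac && p$avc_frac < 1)) {
    abort("valve timing must satisfy 0 < avo_frac < avc_frac < 1")
  }
  structure(p, class = "synth_params")
}

#' @export
print.synth_params <- function(x, ...) {
  cat("<synth_params>\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

## Piecewise raised-cosine interpolation through (knot_t, knot_y): each
## inter-knot segment is a half-cosine, monotone between its endpoints with
## zero slope at every knot, so the assembled curve is smooth (C1) and its
## cumulative positive increment between two knots is exactly
## max(0, y_b - y_a). Knot times are 0-based frames, strictly increasing.
cosine_knot_curve <- function(t, knot_t, knot_y) {
  stopifnot(length(knot_t) == length(knot_y), all(diff(knot_t) > 0))
  y <- numeric(length(t))
  y[t <= knot_t[1]] <- knot_y[1]
  y[t >= knot_t[length(knot_t)]] <- knot_y[length(knot_y)]
  for (i in seq_len(length(knot_t) - 1L)) {
    ta <- knot_t[i]; tb <- knot_t[i + 1L]
    ya <- knot_y[i]; yb <- knot_y[i + 1L]
    in_seg <- t >= ta & t <= tb  # endpoints agree across segments
    y[in_seg] <- ya + (yb - ya) * 0.5 * (1 - cos(pi * (t[in_seg] - ta) / (tb - ta)))
  }
  y
}

## Control waveform: 0 at the ED frame, monotone shortening to `peak` at
## aortic valve closure, smooth diastolic return to 0 at the final frame.
control_waveform <- function(t, avc, t_last, peak) {
  cosine_knot_curve(t, c(0, avc, t_last), c(0, peak, 0))
}

#' Generate one synthetic subject
#'
#' Control subjects follow a smooth shorten--relax waveform per segment,
#' monotone from the end-diastolic reference to peak shortening at aortic
#' valve closure (so noise-free controls have exactly zero systolic stretch).
#' LBBB-like subjects additionally show septal rebound stretch during
#' ejection (on the anteroseptal and inferoseptal segments) and lateral
#' pre-ejection stretch with delayed peak shortening (on the anterolateral
#' and inferolateral segments). Additive Gaussian frame noise is applied and
#' curves are re-referenced so strain at the end-diastolic frame is exactly 0.
#'
#' Consumes the current RNG stream; call [generate_cohort()] for a seeded,
#' reproducible cohort.
#'
#' @param params A [synth_params()] object.
#' @param group `"LBBB"` or `"control"`.
#' @param subject_id Identifier for the generated subject.
#' @return A list as returned by [subject_curves()] plus `subject_id`.
#' @export
generate_subject <- function(params, group = c("LBBB", "control"),
                             subject_id = "S1") {
  stopifnot(inherits(params, "synth_params"))
  group <- match.arg(group)
  n <- params$n_frames
  t <- 0:(n - 1)
  t_last <- n - 1L
  avo <- max(1L, as.integer(round(params$avo_frac * t_last)))
  avc <- min(max(avo + 1L, as.integer(round(params$avc_frac * t_last))),
             t_last - 1L)
  delay <- as.integer(round(params$lbbb_lateral_delay_frac * t_last))

  peaks <- params$peak_strain_pct + rnorm(6, 0, params$peak_strain_sd)
  peaks <- pmin(peaks, -1) # keep shortening waveforms shortening

  ## With all LBBB effect sizes at zero the LBBB path must coincide with the
  ## control construction, so a zero-effect "LBBB" arm is a true null.
  lbbb_effects <- group == "LBBB" &&
    !(params$lbbb_rebound_amp_pct == 0 &&
        params$lbbb_prestretch_amp_pct == 0 && delay == 0L)

  t_mid <- max(avo + 1L, as.integer(floor((avo + avc) / 2)))  # rebound apex
  t_late <- max(t_mid + 1L, min(avc + delay, t_last - 1L))    # delayed peak

  strain <- matrix(0, nrow = 6, ncol = n, dimnames = list(SEGMENTS, NULL))
  for (j in seq_along(SEGMENTS)) {
    seg <- SEGMENTS[j]
    if (lbbb_effects && seg %in% SEPTAL_SEGMENTS) {
      ## early unopposed shortening to a partial dip at AVO, rebound stretch
      ## of the stated amplitude during ejection, then late re-shortening
      dip <- 0.4 * peaks[j]
      y <- cosine_knot_curve(
        t, c(0, avo, t_mid, t_late, t_last),
        c(0, dip, dip + params$lbbb_rebound_amp_pct, peaks[j], 0)
      )
    } else if (lbbb_effects && seg %in% LATERAL_SEGMENTS) {
      ## pre-ejection stretch peaking at AVO, then delayed peak shortening
      y <- cosine_knot_curve(
        t, c(0, avo, t_late, t_last),
        c(0, params$lbbb_prestretch_amp_pct, peaks[j], 0)
      )
    } else {
      y <- control_waveform(t, avc, t_last, peaks[j])
    }
    strain[j, ] <- y
  }
  if (params$noise_sd_pct > 0) {
    strain <- strain + matrix(rnorm(6 * n, 0, params$noise_sd_pct), 6, n)
  }
  strain <- strain - strain[, 1] # exact zero at the ED reference frame

  list(subject_id = subject_id, group = group, strain = strain,
       ed_frame = 0L, avo_frame = as.integer(avo), avc_frame = as.integer(avc))
}

#' Generate a synthetic strain cohort
#'
#' Generates `n_lbbb` LBBB-like and `n_control` normally activated subjects
#' with a single seeded RNG stream threaded through subjects in a fixed order
#' (all LBBB subjects, then all controls), so cohorts are bit-reproducible
#' given the seed. Provenance records the parameters and seed.
#'
#' @param params A [synth_params()] object.
#' @return A [strain_cohort()] whose every subject passes
#'   [validate_cohort()].
#' @export
#' @examples
#' cohort <- generate_cohort(synth_params(n_lbbb = 2, n_control = 2, seed = 7))
#' cohort
generate_cohort <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(params$seed)

  ids_lbbb <- sprintf("LBBB%03d", seq_len(params$n_lbbb))
  ids_ctrl <- sprintf("CTRL%03d", seq_len(params$n_control))
  subjects <- c(
    lapply(ids_lbbb, function(id) generate_subject(params, "LBBB", id)),
    lapply(ids_ctrl, function(id) generate_subject(params, "control", id))
  )

  strain <- purrr::map_dfr(subjects, function(su) {
    tibble::tibble(
      subject_id = su$subject_id,
      group = su$group,
      segment = rep(SEGMENTS, each = ncol(su$strain)),
      frame = rep(seq_len(ncol(su$strain)) - 1L, times = 6),
      strain_pct = as.vector(t(su$strain))
    )
  })
  events <- purrr::map_dfr(subjects, function(su) {
    tibble::tibble(
      subject_id = su$subject_id, group = su$group,
      ed_frame = su$ed_frame, avo_frame = su$avo_frame,
      avc_frame = su$avc_frame
    )
  })
  prov <- paste0(
    "synthetic cohort; seed=", params$seed, "; ",
    paste0(names(unclass(params)), "=",
           vapply(unclass(params), format, character(1)), collapse = ", ")
  )
  strain_cohort(strain, events, provenance = prov)
}
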