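#' Build a strain cohort from tidy tables
#'
#' A strain cohort holds per-subject segmental circumferential strain
#' time-series for the six mid-ventricular AHA segments, together with the
#' per-subject cardiac-cycle event annotations (end-diastolic reference frame,
#' aortic valve opening and closure). Strain is Lagrangian circumferential
#' strain in percent, referenced to the end-diastolic frame (shortening is
#' negative). Frame indices are 0-based throughout the package and the
#' on-disk exchange format.
#'
#' @param strain A data frame with columns `subject_id`, `group` (one of
#'   `"LBBB"`, `"control"`), `segment` (one of [aha_segments()]), `frame`
#'   (0-based integer) and `strain_pct`.
#' @param events A data frame with columns `subject_id`, `ed_frame`,
#'   `avo_frame`, `avc_frame` (0-based frame indices of the end-diastolic
#'   reference, aortic valve opening and aortic valve closure).
#' @param provenance Free-text metadata (source description; generator
#'   parameters and seed for synthetic cohorts).
#' @param validate If `TRUE` (default), error when [validate_cohort()] finds
#'   any violation.
#'
#' @return An object of class `strain_cohort`: a list with tibbles `strain`
#'   and `events` (rows ordered by subject, canonical segment order, frame)
#'   and the `provenance` string.
#' @seealso [read_cohort()], [write_cohort()], [validate_cohort()],
#'   [generate_cohort()]
#' @export
strain_cohort <- function(strain, events, provenance = "unspecified",
                          validate = TRUE) {
  strain <- tibble::as_tibble(strain)
  events <- tibble::as_tibble(events)
  need_s <- c("subject_id", "group", "segment", "frame", "strain_pct")
  need_e <- c("subject_id", "ed_frame", "avo_frame", "avc_frame")
  if (!all(need_s %in% names(strain))) {
    abort(paste0("`strain` must have columns: ", paste(need_s, collapse = ", ")))
  }
  if (!all(need_e %in% names(events))) {
    abort(paste0("`events` must have columns: ", paste(need_e, collapse = ", ")))
  }
  if (nrow(events) == 0L) abort("a strain cohort must contain at least one subject")

  strain <- strain |>
    dplyr::mutate(
      subject_id = as.character(.data$subject_id),
      group = as.character(.data$group),
      segment = as.character(.data$segment),
      frame = as.integer(.data$frame),
      strain_pct = as.numeric(.data$strain_pct)
    ) |>
    dplyr::arrange(
      .data$subject_id,
      match(.data$segment, SEGMENTS),
      .data$frame
    )
  events <- events |>
    dplyr::mutate(
      subject_id = as.character(.data$subject_id),
      dplyr::across(dplyr::all_of(c("ed_frame", "avo_frame", "avc_frame")),
                    as.integer)
    ) |>
    dplyr::arrange(.data$subject_id)

  x <- structure(
    list(strain = strain, events = events,
         provenance = as.character(provenance)[1]),
    class = "strain_cohort"
  )
  if (validate) {
    v <- validate_cohort(x)
    if (nrow(v) > 0L) {
      abort(paste0(
        "invalid strain cohort:\n",
        paste0("- [", v$subject_id, "] ", v$field, ": ", v$message,
               collapse = "\n")
      ))
    }
  }
  x
}

#' @export
print.strain_cohort <- function(x, ...) {
  ns <- cohort_subject_ids(x)
  grp <- table(x$events$group %||% subject_groups(x))
  cat("<strain_cohort> ", length(ns), " subjects (",
      paste(names(grp), grp, sep = ": ", collapse = ", "), ")\n", sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

cohort_subject_ids <- function(cohort) unique(cohort$events$subject_id)

subject_groups <- function(cohort) {
  g <- cohort$strain |>
    dplyr::distinct(.data$subject_id, .data$group)
  setNames(g$group, g$subject_id)
}

#' Extract one subject's curves as a segment-by-frame matrix
#'
#' @param cohort A [strain_cohort()].
#' @param subject_id Subject identifier.
#' @return A list with `strain` (6 x n matrix, rows in canonical segment
#'   order, columns frames 0..n-1), `group`, and the 0-based event frames
#'   `ed_frame`, `avo_frame`, `avc_frame`.
#' @export
subject_curves <- function(cohort, subject_id) {
  stopifnot(inherits(cohort, "strain_cohort"))
  s <- cohort$strain[cohort$strain$subject_id == subject_id, , drop = FALSE]
  e <- cohort$events[cohort$events$subject_id == subject_id, , drop = FALSE]
  if (nrow(s) == 0L || nrow(e) == 0L) {
    abort(paste0("subject '", subject_id, "' not found in cohort"))
  }
  frames <- sort(unique(s$frame))
  mat <- matrix(NA_real_, nrow = length(SEGMENTS), ncol = length(frames),
                dimnames = list(SEGMENTS, frames))
  for (seg in SEGMENTS) {
    row <- s[s$segment == seg, , drop = FALSE]
    mat[seg, ] <- row$strain_pct[order(row$frame)]
  }
  list(
    strain = mat,
    group = s$group[1],
    ed_frame = e$ed_frame[1],
    avo_frame = e$avo_frame[1],
    avc_frame = e$avc_frame[1]
  )
}

cohort_subject_list <- function(cohort) {
  ids <- cohort_subject_ids(cohort)
  setNames(lapply(ids, function(id) subject_curves(cohort, id)), ids)
}

#' Validate a strain cohort against its invariants
#'
#' Checks every subject against the data-model invariants: exactly six
#' segments in the canonical order, a complete common frame grid per subject,
#' strain exactly zero (to `tol`) at the end-diastolic reference frame, event
#' ordering `0 <= ed_frame <= avo_frame < avc_frame < n_frames`, finite
#' strain within \[-100, +300\] percent, unique subject ids and recognised
#' group labels. Validation never raises; it reports.
#'
#' @param cohort A `strain_cohort` (or a list with `strain`/`events` tibbles).
#' @param tol Tolerance for the zero-strain-at-ED check (default `1e-9`).
#' @return A tibble with columns `subject_id`, `field`, `message`; zero rows
#'   when the cohort is valid.
#' @export
validate_cohort <- function(cohort, tol = 1e-9) {
  out <- list()
  add <- function(subject_id, field, message) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      subject_id = subject_id, field = field, message = message
    )
  }
  strain <- cohort$strain
  events <- cohort$events

  if (anyDuplicated(events$subject_id)) {
    dup <- unique(events$subject_id[duplicated(events$subject_id)])
    for (d in dup) add(d, "subject_id", "duplicated subject id in events")
  }
  bad_group <- unique(strain$group[!strain$group %in% GROUP_LEVELS])
  for (g in bad_group) {
    ids <- unique(strain$subject_id[strain$group == g])
    for (id in ids) {
      add(id, "group", paste0("unknown group label '", g, "'"))
    }
  }

  dup_rows <- strain |>
    dplyr::count(.data$subject_id, .data$segment, .data$frame) |>
    dplyr::filter(.data$n > 1L)
  for (i in seq_len(nrow(dup_rows))) {
    add(dup_rows$subject_id[i], "strain",
        paste0("duplicate rows for segment '", dup_rows$segment[i],
               "', frame ", dup_rows$frame[i]))
  }

  ids <- union(unique(strain$subject_id), events$subject_id)
  for (id in ids) {
    s <- strain[strain$subject_id == id, , drop = FALSE]
    e <- events[events$subject_id == id, , drop = FALSE]
    if (nrow(s) == 0L) {
      add(id, "strain", "subject present in events but has no strain rows")
      next
    }
    if (nrow(e) == 0L) {
      add(id, "events", "subject present in strain but has no event row")
      next
    }
    segs <- unique(s$segment)
    missing_seg <- setdiff(SEGMENTS, segs)
    extra_seg <- setdiff(segs, SEGMENTS)
    if (length(missing_seg) > 0L) {
      add(id, "segment",
          paste0("missing segment(s): ", paste(missing_seg, collapse = ", ")))
    }
    if (length(extra_seg) > 0L) {
      add(id, "segment",
          paste0("unknown segment(s): ", paste(extra_seg, collapse = ", "),
                 " (expected exactly 6 AHA mid-ventricular segments)"))
    }
    if (length(missing_seg) > 0L || length(extra_seg) > 0L) next

    frames <- sort(unique(s$frame))
    n <- length(frames)
    if (!identical(frames, seq(0L, n - 1L))) {
      add(id, "frame", "frames must be the contiguous 0-based grid 0..n-1")
      next
    }
    per_seg <- table(s$segment)
    if (any(per_seg != n)) {
      add(id, "frame", "segments do not share a common frame grid")
      next
    }

    ed <- e$ed_frame[1]; avo <- e$avo_frame[1]; avc <- e$avc_frame[1]
    if (is.na(ed) || is.na(avo) || is.na(avc) ||
        !(0L <= ed && ed <= avo && avo < avc && avc < n)) {
      add(id, "events",
          paste0("event frames must satisfy 0 <= ed (", ed, ") <= avo (", avo,
                 ") < avc (", avc, ") < n_frames (", n, ")"))
      next
    }

    if (any(!is.finite(s$strain_pct))) {
      add(id, "strain_pct", "non-finite strain values")
      next
    }
    if (any(s$strain_pct < -100 | s$strain_pct > 300)) {
      bad <- s$strain_pct[s$strain_pct < -100 | s$strain_pct > 300][1]
      add(id, "strain_pct",
          paste0("strain out of physiological range [-100, 300]%: ", bad))
    }
    ed_strain <- s$strain_pct[s$frame == ed]
    if (any(abs(ed_strain) > tol)) {
      seg_bad <- s$segment[s$frame == ed][abs(ed_strain) > tol][1]
      add(id, "ed_frame",
          paste0("strain at the end-diastolic reference frame must be 0; ",
                 "segment '", seg_bad, "' has ",
                 format(ed_strain[abs(ed_strain) > tol][1])))
    }
  }

  if (length(out) == 0L) {
    tibble::tibble(subject_id = character(), field = character(),
                   message = character())
  } else {
    dplyr::bind_rows(out)
  }
}
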