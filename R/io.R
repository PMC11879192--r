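#' Read a strain cohort from the exchange format
#'
#' Two on-disk formats are supported. `long_csv`: a long-format CSV with
#' columns `subject_id, group, segment, frame, strain_pct` plus a sidecar
#' `events.csv` (columns `subject_id, ed_frame, avo_frame, avc_frame`) in the
#' same directory. `json`: a single JSON file with one object per subject
#' holding the per-segment strain arrays and integer event fields. Frame
#' indices are 0-based. Segment rows are re-ordered into the canonical
#' circumferential order regardless of file order.
#'
#' Because different tools use different end-diastolic conventions, strain is
#' required to be zero at `ed_frame`. With `re_reference = TRUE` curves are
#' re-referenced at load (the strain value at `ed_frame` is subtracted,
#' per segment); with the default `FALSE`, non-zero strain at `ed_frame`
#' beyond `1e-9` is a format error naming the subject.
#'
#' @param path File path (`long_csv`: the strain CSV; `json`: the JSON file).
#' @param format `"long_csv"` or `"json"`.
#' @param events_path Path of the events sidecar for `long_csv`; defaults to
#'   `events.csv` next to `path`.
#' @param re_reference Re-reference strain to `ed_frame` instead of erroring
#'   on a non-zero ED strain.
#' @return A [strain_cohort()].
#' @export
read_cohort <- function(path, format = c("long_csv", "json"),
                        events_path = NULL, re_reference = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file does not exist: ", path))

  if (format == "long_csv") {
    strain <- readr::read_csv(
      path,
      col_types = readr::cols(
        subject_id = readr::col_character(),
        group = readr::col_character(),
        segment = readr::col_character(),
        frame = readr::col_integer(),
        strain_pct = readr::col_double()
      )
    )
    if (is.null(events_path)) {
      events_path <- file.path(dirname(path), "events.csv")
    }
    if (!file.exists(events_path)) {
      abort(paste0("events sidecar not found: ", events_path))
    }
    events <- readr::read_csv(
      events_path,
      col_types = readr::cols(
        subject_id = readr::col_character(),
        ed_frame = readr::col_integer(),
        avo_frame = readr::col_integer(),
        avc_frame = readr::col_integer()
      )
    )
    provenance <- paste0("read from ", path)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    subjects <- obj$subjects
    if (is.null(subjects)) abort("json cohort must have a 'subjects' array")
    strain <- purrr::map_dfr(subjects, function(su) {
      segs <- names(su$strain)
      purrr::map_dfr(segs, function(seg) {
        v <- as.numeric(su$strain[[seg]])
        tibble::tibble(
          subject_id = su$subject_id, group = su$group, segment = seg,
          frame = seq_along(v) - 1L, strain_pct = v
        )
      })
    })
    events <- purrr::map_dfr(subjects, function(su) {
      tibble::tibble(
        subject_id = su$subject_id,
        ed_frame = as.integer(su$ed_frame),
        avo_frame = as.integer(su$avo_frame),
        avc_frame = as.integer(su$avc_frame)
      )
    })
    provenance <- as.character(obj$provenance %||% paste0("read from ", path))
  }

  if (re_reference) {
    ed <- setNames(events$ed_frame, events$subject_id)
    strain <- strain |>
      dplyr::group_by(.data$subject_id, .data$segment) |>
      dplyr::mutate(
        strain_pct = .data$strain_pct -
          .data$strain_pct[match(ed[.data$subject_id[1]], .data$frame)]
      ) |>
      dplyr::ungroup()
  }

  cohort <- strain_cohort(strain, events, provenance = provenance,
                          validate = FALSE)
  v <- validate_cohort(cohort)
  if (nrow(v) > 0L) {
    abort(paste0(
      "cohort file fails format validation:\n",
      paste0("- [", v$subject_id, "] ", v$field, ": ", v$message,
             collapse = "\n")
    ))
  }
  cohort
}

#' Write a strain cohort in the exchange format
#'
#' Output is deterministic: rows are ordered by subject id, canonical segment
#' order, frame, so the same cohort always produces identical bytes.
#'
#' @param cohort A [strain_cohort()].
#' @param path Output path (`long_csv`: the strain CSV; the events sidecar is
#'   written as `events.csv` next to it; `json`: the JSON file).
#' @param format `"long_csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("long_csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(cohort, "strain_cohort"))
  if (nrow(cohort$events) == 0L) abort("refusing to write an empty cohort")

  strain <- cohort$strain |>
    dplyr::arrange(.data$subject_id, match(.data$segment, SEGMENTS),
                   .data$frame)
  events <- cohort$events |>
    dplyr::select(dplyr::all_of(c("subject_id", "ed_frame", "avo_frame",
                                  "avc_frame"))) |>
    dplyr::arrange(.data$subject_id)

  if (format == "long_csv") {
    readr::write_csv(strain, path)
    readr::write_csv(events, file.path(dirname(path), "events.csv"))
  } else {
    subj <- cohort_subject_list(cohort)
    subjects <- purrr::imap(subj, function(su, id) {
      list(
        subject_id = id,
        group = su$group,
        ed_frame = su$ed_frame,
        avo_frame = su$avo_frame,
        avc_frame = su$avc_frame,
        strain = lapply(
          setNames(SEGMENTS, SEGMENTS),
          function(seg) unname(su$strain[seg, ])
        )
      )
    })
    jsonlite::write_json(
      list(provenance = cohort$provenance, subjects = unname(subjects)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}
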