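# Dataset manifests and round assembly.
#
# A manifest is the JSON document that ties a cohort together: subjects with
# their recording protocol ("adl_rounds": discrete bouts of activities of
# daily living, at most 5 min per round; "continuous": free-living streams,
# at most 10 min per round), per-round sensor file paths, the seven UPDRS-III
# tremor items labelling each round, medication state and timestamps of the
# clinical assessments so that recording made *during* an assessment can be
# excluded from analysis.

ROUND_CAP_S <- c(adl_rounds = 300, continuous = 600)

label_item_names <- c("rest_head", "rest_hand_left", "rest_hand_right",
                      "rest_leg_left", "rest_leg_right",
                      "action_hand_left", "action_hand_right")

#' Read a cohort manifest
#'
#' @param path path to a manifest JSON file.
#' @return a `tremor_manifest` object (nested list of subjects and rounds).
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(m$subjects)) stop("manifest has no 'subjects' entry")
  ids <- vapply(m$subjects, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject_id in manifest")
  attr(m, "dir") <- dirname(normalizePath(path))
  class(m) <- "tremor_manifest"
  m
}

#' Write a cohort manifest
#'
#' @param manifest a `tremor_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  m <- unclass(manifest)
  attr(m, "dir") <- NULL
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Summarize a manifest's composition
#'
#' @param manifest a `tremor_manifest`.
#' @return a data.frame with one row per subject: `subject_id`, `protocol`,
#'   `n_rounds`, `duration_min`.
#' @export
cohort_summary <- function(manifest) {
  rows <- lapply(manifest$subjects, function(s) {
    data.frame(subject_id = s$subject_id, protocol = s$protocol,
               n_rounds = length(s$rounds),
               duration_min = sum(vapply(s$rounds, function(r)
                 as.numeric(r$duration_s), numeric(1))) / 60,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-round metadata table
#'
#' Flattens a manifest into one row per round, carrying subject identity,
#' protocol, sex, medication state and the seven tremor items. This is the
#' `rounds` table consumed by [tremor_fit()] and the evaluation protocols.
#'
#' @param manifest a `tremor_manifest`.
#' @return a data.frame, one row per round.
#' @export
round_table <- function(manifest) {
  rows <- lapply(manifest$subjects, function(s) {
    do.call(rbind, lapply(s$rounds, function(r) {
      lb <- r$labels
      df <- data.frame(subject_id = s$subject_id,
                       round_index = as.integer(r$round_index),
                       protocol = s$protocol,
                       sex = if (is.null(s$sex)) NA_character_ else s$sex,
                       most_affected_side = s$most_affected_side,
                       med_state = if (is.null(r$med_state)) "unknown" else r$med_state,
                       duration_s = as.numeric(r$duration_s),
                       stringsAsFactors = FALSE)
      for (nm in label_item_names)
        df[[nm]] <- if (is.null(lb[[nm]])) 0L else as.integer(lb[[nm]])
      df
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Construct a labeled round record
#'
#' @param subject_id subject identifier.
#' @param round_index round number within subject (1-based).
#' @param wrist,ankle [gyro_recording()]s of the two sites (same rate).
#' @param labels a [tremor_labels()].
#' @param med_state `"pre_medication"`, `"post_medication"` or `"unknown"`.
#' @return an object of class `round_record`.
#' @export
round_record <- function(subject_id, round_index, wrist, ankle, labels,
                         med_state = c("unknown", "pre_medication",
                                       "post_medication")) {
  med_state <- match.arg(med_state)
  stopifnot(inherits(wrist, "gyro_recording"), inherits(ankle, "gyro_recording"),
            inherits(labels, "tremor_labels"))
  if (wrist$sampling_rate_hz != ankle$sampling_rate_hz)
    stop("wrist and ankle recordings must share a sampling rate")
  structure(list(subject_id = as.character(subject_id),
                 round_index = as.integer(round_index),
                 wrist = wrist, ankle = ankle, labels = labels,
                 med_state = med_state,
                 duration_s = duration_s(wrist)),
            class = "round_record")
}

#' @export
print.round_record <- function(x, ...) {
  cat(sprintf("<round_record> subject=%s round=%d  %.1f s  med=%s  total=%d\n",
              x$subject_id, x$round_index, x$duration_s, x$med_state,
              tremor_target(x$labels, "total")))
  invisible(x)
}

labels_from_entry <- function(r, side) {
  lb <- r$labels
  get <- function(nm) if (is.null(lb[[nm]])) 0L else as.integer(lb[[nm]])
  tremor_labels(get("rest_head"), get("rest_hand_left"), get("rest_hand_right"),
                get("rest_leg_left"), get("rest_leg_right"),
                get("action_hand_left"), get("action_hand_right"),
                most_affected_side = side)
}

drop_intervals <- function(rec, intervals) {
  if (!length(intervals)) return(rec)
  fs <- rec$sampling_rate_hz
  t <- rec$t0 + (seq_len(n_samples(rec)) - 1) / fs
  keep <- rep(TRUE, length(t))
  for (iv in intervals) {
    iv <- as.numeric(unlist(iv))
    keep[t >= iv[1] & t < iv[2]] <- FALSE
  }
  rec$axes <- rec$axes[keep, , drop = FALSE]
  rec
}

truncate_rec <- function(rec, cap_s) {
  n_cap <- floor(cap_s * rec$sampling_rate_hz)
  if (n_samples(rec) > n_cap) rec$axes <- rec$axes[seq_len(n_cap), , drop = FALSE]
  rec
}

#' Assemble preprocessed, labeled rounds from a manifest
#'
#' Loads each round's wrist and ankle files, drops samples overlapping the
#' flagged clinical-assessment intervals, truncates to the protocol's round
#' cap (300 s for `adl_rounds` subjects, 600 s for `continuous` subjects)
#' and band-pass filters both recordings. Rounds without labels (no
#' associable assessment) are excluded with a warning. Deterministic given
#' the manifest.
#'
#' @param manifest a `tremor_manifest` (as returned by [read_manifest()]).
#' @param dir directory the round file paths are relative to; defaults to the
#'   directory the manifest was read from.
#' @param filter apply [bandpass_filter()] (default TRUE).
#' @return a list of [round_record()]s.
#' @export
assemble_rounds <- function(manifest, dir = attr(manifest, "dir"),
                            filter = TRUE) {
  out <- list()
  for (s in manifest$subjects) {
    cap <- ROUND_CAP_S[[s$protocol]]
    for (r in s$rounds) {
      if (is.null(r$labels)) {
        warning("round ", r$round_index, " of subject ", s$subject_id,
                " has no associable assessment; excluded")
        next
      }
      wrist <- load_recording(file.path(dir, r$wrist_file), "wrist",
                              sampling_rate_hz = manifest$sampling_rate_hz %||% 64)
      ankle <- load_recording(file.path(dir, r$ankle_file), "ankle",
                              sampling_rate_hz = manifest$sampling_rate_hz %||% 64)
      iv <- r$excluded_intervals
      wrist <- truncate_rec(drop_intervals(wrist, iv), cap)
      ankle <- truncate_rec(drop_intervals(ankle, iv), cap)
      if (filter) {
        wrist <- bandpass_filter(wrist)
        ankle <- bandpass_filter(ankle)
      }
      out[[length(out) + 1L]] <-
        round_record(s$subject_id, r$round_index, wrist, ankle,
                     labels_from_entry(r, s$most_affected_side),
                     med_state = r$med_state %||% "unknown")
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
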