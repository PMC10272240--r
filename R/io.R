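#' Load a recording from EDF or CSV
#'
#' CSV files carry one column per channel (header row = channel labels) and
#' one row per sample; the sampling rate is not part of the CSV dialect and
#' is supplied via `fs` (default 128 Hz). EDF files carry their own rate.
#' Channels are reordered to montage order; missing or extra channels are
#' errors.
#'
#' @param path file to read.
#' @param format `"edf"` or `"csv"`; default guessed from the extension.
#' @param fs sampling rate for CSV input (ignored for EDF).
#' @param montage montage whose channel set and order the recording must match.
#' @param subject_id optional subject identifier override.
#' @return An [new_recording()] object.
#' @export
load_recording <- function(path, format = c("auto", "edf", "csv"), fs = 128,
                           montage = default_montage(), subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("edf", "csv")) {
      abort(sprintf("unknown recording format '%s'", ext), "eegtrp_unknown_format")
    }
    format <- ext
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), "eegtrp_io_error")

  if (format == "edf") {
    raw <- read_edf(path, subject_id = subject_id)
    samples <- raw$samples
    labels <- raw$channel_labels
    fs <- raw$fs
    subject_id <- raw$subject_id
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    if (!all(vapply(df, is.numeric, TRUE))) {
      abort("CSV recording contains non-numeric samples", "eegtrp_nonnumeric_samples")
    }
    samples <- t(as.matrix(df))
    labels <- colnames(df)
    subject_id <- subject_id %||% sub("\\.csv$", "", basename(path))
  }

  missing <- setdiff(montage$electrodes, labels)
  extra <- setdiff(labels, montage$electrodes)
  if (length(missing) > 0) {
    abort(paste("recording is missing channels:", paste(missing, collapse = ", ")),
          "eegtrp_missing_channel")
  }
  if (length(extra) > 0) {
    abort(paste("recording has unknown channels:", paste(extra, collapse = ", ")),
          "eegtrp_extra_channel")
  }
  samples <- samples[match(montage$electrodes, labels), , drop = FALSE]
  new_recording(samples, fs = fs, channel_labels = montage$electrodes,
                subject_id = subject_id %||% "unknown")
}

#' Save a recording to EDF or CSV
#'
#' The written file round-trips through [load_recording()]: bit-exactly for
#' CSV, and within the 16-bit quantisation step (well below 0.1 uV at EEG
#' amplitude ranges) for EDF.
#'
#' @param recording an [new_recording()] object.
#' @param path destination file.
#' @param format `"edf"` or `"csv"`; default guessed from the extension.
#' @export
save_recording <- function(recording, path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("edf", "csv")) {
      abort(sprintf("unknown recording format '%s'", ext), "eegtrp_unknown_format")
    }
    format <- ext
  }
  if (format == "edf") {
    write_edf(recording, path)
  } else {
    df <- as.data.frame(t(recording$samples))
    colnames(df) <- recording$channel_labels
    # %.17g round-trips IEEE doubles exactly, making CSV output bit-exact
    df[] <- lapply(df, function(col) sprintf("%.17g", col))
    ok <- tryCatch({
      utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("cannot write '%s'", path), "eegtrp_io_error")
  }
  invisible(path)
}

EVENT_MARKERS <- c("baseline_start", "baseline_end", "drawing_shown",
                   "first_sketch_element", "task_end")

#' Load and validate an experiment event log
#'
#' The event log (CSV with columns `time_s`, `marker`, `condition`,
#' `task_index`) drives epoch segmentation. Markers must be time-sorted;
#' every `drawing_shown` must be followed by a `first_sketch_element` and a
#' `task_end` for the same task; every `baseline_start` needs a matching
#' `baseline_end`, and baselines must last about 20 s (the fixation-cross
#' duration) within `baseline_tol_s`.
#'
#' @param path CSV file, or a data frame with the same columns.
#' @param baseline_duration_s nominal baseline length (seconds).
#' @param baseline_tol_s accepted deviation from the nominal length.
#' @return An object of class `eeg_events` (validated, time-sorted data frame).
#' @export
load_events <- function(path, baseline_duration_s = 20, baseline_tol_s = 1) {
  ev <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "marker", "condition", "task_index")
  if (!all(need %in% names(ev))) {
    abort(paste("event log must have columns:", paste(need, collapse = ", ")),
          "eegtrp_bad_event_schema")
  }
  if (is.unsorted(ev$time_s, strictly = FALSE)) {
    abort("event times are not sorted", "eegtrp_unsorted_events")
  }
  if (!all(ev$marker %in% EVENT_MARKERS)) {
    abort(paste("unknown markers:",
                paste(unique(setdiff(ev$marker, EVENT_MARKERS)), collapse = ", ")),
          "eegtrp_unknown_marker")
  }
  cond <- ev$condition[ev$marker %in% c("drawing_shown", "first_sketch_element", "task_end")]
  if (!all(cond %in% c("isometric", "orthographic"))) {
    abort("condition labels must be 'isometric' or 'orthographic'",
          "eegtrp_unknown_condition")
  }

  # baseline pairing
  bs <- ev[ev$marker == "baseline_start", ]
  be <- ev[ev$marker == "baseline_end", ]
  if (nrow(bs) != nrow(be)) {
    abort("unmatched baseline_start/baseline_end markers", "eegtrp_orphan_marker")
  }
  if (nrow(bs) > 0) {
    dur <- be$time_s - bs$time_s
    if (any(dur <= 0)) abort("baseline_end precedes baseline_start", "eegtrp_orphan_marker")
    if (any(abs(dur - baseline_duration_s) > baseline_tol_s)) {
      abort(sprintf("baseline duration outside %g +/- %g s",
                    baseline_duration_s, baseline_tol_s),
            "eegtrp_bad_baseline_duration")
    }
  }

  # task triple pairing
  for (ti in unique(ev$task_index[ev$marker == "drawing_shown"])) {
    tev <- ev[ev$task_index == ti & ev$marker %in%
                c("drawing_shown", "first_sketch_element", "task_end"), ]
    if (!identical(tev$marker, c("drawing_shown", "first_sketch_element", "task_end"))) {
      abort(sprintf("task %s markers incomplete or out of order", ti),
            "eegtrp_orphan_marker")
    }
    if (length(unique(tev$condition)) != 1L) {
      abort(sprintf("task %s has inconsistent condition labels", ti),
            "eegtrp_unknown_condition")
    }
  }
  class(ev) <- c("eeg_events", "data.frame")
  ev
}

#' Save an event log to CSV
#' @param events an `eeg_events` object or compatible data frame.
#' @param path destination CSV.
#' @export
save_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}
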