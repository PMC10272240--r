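#' Construct a continuous multichannel EEG recording
#'
#' A recording holds a channels-by-time matrix of samples in microvolts,
#' its sampling rate, channel labels in montage order, and a subject
#' identifier. The study's headset samples at 128 Hz; other rates are
#' accepted but flagged with a warning so that downstream defaults
#' (window lengths in samples) remain auditable.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `samples`.
#' @param subject_id identifier for the subject/session.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(samples, fs, channel_labels = default_montage()$electrodes,
                          subject_id = "S01") {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric channels x time matrix", "eegtrp_bad_samples")
  }
  if (length(channel_labels) != nrow(samples)) {
    abort("number of channel labels must equal number of sample rows",
          "eegtrp_channel_mismatch")
  }
  if (anyNA(samples) || any(!is.finite(samples))) {
    abort("samples contain NA or non-finite values", "eegtrp_nonfinite_samples")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a positive scalar", "eegtrp_bad_fs")
  }
  if (fs != 128) {
    warn_classed(sprintf("sampling rate %g Hz differs from the conventional 128 Hz", fs),
                 "eegtrp_nonstandard_fs")
  }
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels),
         subject_id = subject_id),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

n_samples <- function(recording) ncol(recording$samples)

duration_s <- function(recording) ncol(recording$samples) / recording$fs

#' Construct a labelled epoch
#'
#' An epoch is a slice of a session recording labelled with its role in the
#' experiment: a pre-task `baseline`, the drawing-interpretation segment
#' `seg1`, or the modelling segment `seg2`.
#'
#' @param samples channels x time matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param subject_id subject identifier.
#' @param condition `"isometric"` or `"orthographic"`.
#' @param role `"baseline"`, `"seg1"` or `"seg2"`.
#' @param task_index integer task number within the session.
#' @param t_start_s,t_end_s epoch bounds in session time (seconds).
#' @param channel_labels channel labels, montage order.
#' @return An object of class `eeg_epoch`.
#' @export
new_epoch <- function(samples, fs, subject_id, condition, role, task_index,
                      t_start_s, t_end_s,
                      channel_labels = default_montage()$electrodes) {
  if (t_end_s <= t_start_s) {
    abort("epoch end must be after its start", "eegtrp_negative_epoch")
  }
  condition <- match.arg(condition, c("isometric", "orthographic"))
  role <- match.arg(role, c("baseline", "seg1", "seg2"))
  structure(
    list(samples = samples, fs = fs, subject_id = subject_id,
         condition = condition, role = role, task_index = as.integer(task_index),
         t_start_s = t_start_s, t_end_s = t_end_s,
         channel_labels = channel_labels),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %s task %d %s/%s: [%.3f, %.3f) s, %d samples @ %g Hz\n",
              x$subject_id, x$task_index, x$condition, x$role,
              x$t_start_s, x$t_end_s, ncol(x$samples), x$fs))
  invisible(x)
}
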