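#' Cut a session recording into baseline and task-segment epochs
#'
#' For each task in the event log, three epochs are produced:
#' the pre-task baseline (from its `baseline_start`/`baseline_end` pair, the
#' last baseline ending at or before the task's `drawing_shown`), `seg1`
#' from `drawing_shown` to `first_sketch_element` (interpreting the
#' drawing), and `seg2` from `first_sketch_element` to `task_end`
#' (generating the model). `seg1` ends exactly where `seg2` starts, so the
#' two segments tile the task without gap or overlap. Sample indexing is
#' half-open `[round(t_start*fs), round(t_end*fs))`.
#'
#' @param recording an `eeg_recording` covering the event span.
#' @param events an `eeg_events` log (see [load_events()]).
#' @return List of `eeg_epoch` objects (baseline, seg1, seg2 per task).
#' @export
segment_session <- function(recording, events) {
  events <- if (inherits(events, "eeg_events")) events else load_events(events)
  fs <- recording$fs
  nt <- ncol(recording$samples)

  slice <- function(t0, t1, condition, role, task_index) {
    if (t1 <= t0) {
      abort(sprintf("negative-length %s segment for task %d", role, task_index),
            "eegtrp_negative_epoch")
    }
    i0 <- round(t0 * fs)            # 0-based half-open [i0, i1)
    i1 <- round(t1 * fs)
    if (i0 < 0 || i1 > nt) {
      abort(sprintf("%s epoch [%g, %g) s outside the recording", role, t0, t1),
            "eegtrp_epoch_outside_recording")
    }
    new_epoch(recording$samples[, (i0 + 1L):i1, drop = FALSE], fs,
              recording$subject_id, condition, role, task_index, t0, t1,
              channel_labels = recording$channel_labels)
  }

  bs <- events[events$marker == "baseline_start", ]
  be <- events[events$marker == "baseline_end", ]
  tasks <- events[events$marker == "drawing_shown", ]
  epochs <- list()
  for (k in seq_len(nrow(tasks))) {
    ti <- tasks$task_index[k]
    cond <- tasks$condition[k]
    t_draw <- tasks$time_s[k]
    t_sketch <- events$time_s[events$marker == "first_sketch_element" &
                                events$task_index == ti]
    t_end <- events$time_s[events$marker == "task_end" & events$task_index == ti]
    pre <- which(be$time_s <= t_draw)
    if (length(pre) == 0) {
      abort(sprintf("no baseline precedes task %d", ti), "eegtrp_orphan_marker")
    }
    j <- pre[length(pre)]
    epochs <- c(epochs, list(
      slice(bs$time_s[j], be$time_s[j], cond, "baseline", ti),
      slice(t_draw, t_sketch, cond, "seg1", ti),
      slice(t_sketch, t_end, cond, "seg2", ti)
    ))
  }
  epochs
}
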