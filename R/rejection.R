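#' Per-participant amplitude rejection threshold
#'
#' The subject-specific threshold is three standard deviations above the
#' mean of the absolute sample values, pooled over all electrodes and
#' samples of the epoch. Absolute values are used because band-passed EEG is
#' near zero-mean, which would otherwise give a degenerate near-zero
#' threshold.
#'
#' @param epoch an `eeg_epoch` (or a channels x time matrix).
#' @return Threshold in microvolts.
#' @export
subject_threshold <- function(epoch) {
  x <- if (inherits(epoch, "eeg_epoch")) epoch$samples else epoch
  if (length(x) == 0) abort("empty epoch", "eegtrp_empty_epoch")
  a <- abs(as.numeric(x))
  m <- mean(a)
  s <- stats::sd(a)
  if (is.na(s)) s <- 0
  m + 3 * s
}

#' Flag 1 s sliding windows exceeding amplitude criteria
#'
#' A window of `window_s` seconds slides across the epoch one sample at a
#' time. A window is bad when its mean absolute amplitude (over all samples
#' and electrodes) exceeds `min(threshold_uV, abs_limit_uV)`, or when any
#' single sample inside it exceeds `abs_limit_uV` (default 100 uV) in
#' absolute value. A sample is retained only if every window covering it is
#' good, so one bad sample in a clean epoch discards the full
#' `2*window - 1` sample neighbourhood around it.
#'
#' @param epoch an `eeg_epoch` (or channels x time matrix with `fs` given).
#' @param threshold_uV subject-specific threshold (see [subject_threshold()]).
#' @param abs_limit_uV absolute amplitude limit in microvolts (default 100).
#' @param window_s window length in seconds (default 1).
#' @param fs sampling rate, required when `epoch` is a bare matrix.
#' @return An object of class `rejection_result`: list with the per-sample
#'   logical `mask` (TRUE = retained), `threshold_subject_uV`,
#'   `threshold_effective_uV`, and `pct_bad`.
#' @export
mark_bad_windows <- function(epoch, threshold_uV, abs_limit_uV = 100,
                             window_s = 1, fs = NULL) {
  if (inherits(epoch, "eeg_epoch")) {
    x <- epoch$samples
    fs <- epoch$fs
  } else {
    x <- epoch
    if (is.null(fs)) abort("fs required for matrix input", "eegtrp_bad_fs")
  }
  if (threshold_uV < 0) abort("threshold must be non-negative", "eegtrp_bad_threshold")
  nt <- ncol(x)
  wlen <- round(window_s * fs)
  if (nt < wlen) abort("epoch shorter than one rejection window", "eegtrp_signal_too_short")

  thr_eff <- min(threshold_uV, abs_limit_uV)
  a <- abs(x)
  mean_t <- colMeans(a)                          # per-sample cross-electrode mean |x|
  peak_t <- apply(a, 2, max)

  nwin <- nt - wlen + 1L
  cm <- c(0, cumsum(mean_t))
  win_mean <- (cm[(wlen + 1):(nt + 1)] - cm[1:nwin]) / wlen
  ce <- c(0, cumsum(peak_t > abs_limit_uV))
  win_peak_bad <- (ce[(wlen + 1):(nt + 1)] - ce[1:nwin]) > 0
  bad_win <- win_mean > thr_eff | win_peak_bad

  # sample s is bad if any bad window starts in [s - wlen + 1, s]
  cb <- c(0, cumsum(bad_win))
  s <- seq_len(nt)
  lo <- pmax(1L, s - wlen + 1L)
  hi <- pmin(s, nwin)
  covered_bad <- hi >= lo & (cb[pmin(hi, nwin) + 1L] - cb[lo]) > 0
  mask <- !covered_bad

  structure(
    list(mask = mask,
         threshold_subject_uV = threshold_uV,
         threshold_effective_uV = thr_eff,
         pct_bad = 100 * mean(!mask)),
    class = "rejection_result"
  )
}

#' @export
print.rejection_result <- function(x, ...) {
  cat(sprintf("<rejection_result> threshold %.2f uV (effective %.2f), %.2f%% bad\n",
              x$threshold_subject_uV, x$threshold_effective_uV, x$pct_bad))
  invisible(x)
}
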