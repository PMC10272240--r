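#' Frequency bands analysed by the pipeline
#'
#' Theta 4-7 Hz, alpha 8-12 Hz, beta 13-30 Hz.
#' @export
EEG_BANDS <- list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 30))

# Windowed-sinc FIR band-pass design (Hamming window).
# Transition bandwidth: 2 Hz at the low edge; 25% of the high cutoff, capped
# at 12.5 Hz, at the high edge. Order from the narrower transition:
# ntaps = ceil(3.3 / (tb / fs)), forced odd so the filter is a symmetric
# type-I linear-phase design with an integer group delay.
fir_design_bandpass <- function(low_Hz, high_Hz, fs) {
  if (!(low_Hz > 0 && low_Hz < high_Hz && high_Hz < fs / 2)) {
    abort("need 0 < low < high < fs/2 for a band-pass design", "eegtrp_bad_band")
  }
  tb_low <- 2
  tb_high <- min(0.25 * high_Hz, 12.5)
  tb <- min(tb_low, tb_high)
  ntaps <- ceiling(3.3 / (tb / fs))
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  taps <- signal::fir1(ntaps - 1, c(low_Hz, high_Hz) / (fs / 2), type = "pass",
                       window = signal::hamming(ntaps))
  as.numeric(taps)
}

# Zero-phase FIR application: linear convolution (FFT-based) with the group
# delay (ntaps-1)/2 removed, so features stay aligned with their input time.
apply_fir_zerophase <- function(x, taps) {
  ntaps <- length(taps)
  if (length(x) < ntaps) {
    abort("signal shorter than the filter", "eegtrp_signal_too_short")
  }
  d <- (ntaps - 1) / 2
  y <- stats::convolve(x, rev(taps), type = "open")
  y[(d + 1):(d + length(x))]
}

#' Remove DC offset with a first-order IIR high-pass
#'
#' Wireless consumer EEG amplifiers ride on a large DC offset (on the order
#' of thousands of microvolts); a 0.16 Hz first-order high-pass removes it
#' while leaving all analysed bands (>= 4 Hz) essentially untouched
#' (gain at 10 Hz differs from unity by < 0.02%).
#'
#' @param recording an `eeg_recording`.
#' @param fc high-pass cutoff in Hz (default 0.16).
#' @return The filtered recording, same shape.
#' @export
highpass_dc_remove <- function(recording, fc = 0.16) {
  if (fc <= 0) abort("cutoff must be positive", "eegtrp_bad_cutoff")
  if (recording$fs <= 2 * fc) abort("fs must exceed 2*fc", "eegtrp_bad_cutoff")
  bt <- signal::butter(1, fc / (recording$fs / 2), type = "high")
  out <- recording
  out$samples <- t(apply(recording$samples, 1, function(ch) {
    as.numeric(signal::filter(bt, ch))
  }))
  rownames(out$samples) <- recording$channel_labels
  out
}

#' Broadband FIR band-pass filter
#'
#' Hamming windowed-sinc band-pass (default 4-45 Hz, the pipeline's
#' broadband range) applied zero-phase by delay compensation, channel-wise.
#'
#' @param recording an `eeg_recording`.
#' @param low_Hz,high_Hz band edges in Hz.
#' @return The filtered recording, same shape, with the filter half-length
#'   attached as attribute `"edge_samples"` (the edge-transient margin).
#' @export
fir_bandpass <- function(recording, low_Hz = 4, high_Hz = 45) {
  taps <- fir_design_bandpass(low_Hz, high_Hz, recording$fs)
  out <- recording
  out$samples <- t(apply(recording$samples, 1, apply_fir_zerophase, taps = taps))
  rownames(out$samples) <- recording$channel_labels
  attr(out, "edge_samples") <- (length(taps) - 1) / 2
  out
}

#' Band-pass an epoch into a named frequency band
#'
#' Same design rules as [fir_bandpass()], applied to an epoch at the band's
#' edges. The filter half-length is recorded as attribute `"edge_samples"`;
#' [epoch_power()] excludes that margin at both epoch ends from the power
#' average because the convolution has not reached steady state there.
#'
#' @param epoch an `eeg_epoch`.
#' @param band `"theta"`, `"alpha"` or `"beta"`, or a `c(low, high)` pair.
#' @return The band-filtered epoch.
#' @export
band_filter <- function(epoch, band) {
  if (is.character(band)) {
    if (!band %in% names(EEG_BANDS)) {
      abort(sprintf("unknown band '%s'", band), "eegtrp_unknown_band")
    }
    edges <- EEG_BANDS[[band]]
  } else {
    edges <- band
  }
  taps <- fir_design_bandpass(edges[1], edges[2], epoch$fs)
  if (ncol(epoch$samples) < length(taps)) {
    abort(sprintf("epoch too short for the %s-band filter (%d taps)",
                  if (is.character(band)) band else "requested", length(taps)),
          "eegtrp_signal_too_short")
  }
  out <- epoch
  out$samples <- t(apply(epoch$samples, 1, apply_fir_zerophase, taps = taps))
  rownames(out$samples) <- epoch$channel_labels
  attr(out, "edge_samples") <- (length(taps) - 1) / 2
  out
}
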