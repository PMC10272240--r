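#' Mean band power per electrode over retained samples
#'
#' Power is the time-domain mean of squared band-passed samples, computed
#' over retained samples only (rejected spans are excluded, not
#' zero-filled). The filter edge-transient margin recorded by
#' [band_filter()] as `"edge_samples"` is excluded at both epoch ends,
#' because the convolution is not in steady state there and would bias the
#' power estimate downward.
#'
#' @param filtered_epoch a band-filtered `eeg_epoch` (or channels x time matrix).
#' @param mask optional per-sample logical retention mask (TRUE = keep).
#' @param edge_samples margin to drop at each end; defaults to the epoch's
#'   `"edge_samples"` attribute (0 if absent).
#' @return Named numeric vector of powers (uV^2), one per electrode.
#' @export
epoch_power <- function(filtered_epoch, mask = NULL, edge_samples = NULL) {
  x <- if (inherits(filtered_epoch, "eeg_epoch")) filtered_epoch$samples else filtered_epoch
  nt <- ncol(x)
  edge <- edge_samples %||% (attr(filtered_epoch, "edge_samples") %||% 0L)
  keep <- rep(TRUE, nt)
  if (!is.null(mask)) {
    if (length(mask) != nt) abort("mask length must match the epoch", "eegtrp_bad_mask")
    keep <- keep & mask
  }
  if (edge > 0 && nt > 2 * edge) {
    keep[c(seq_len(edge), (nt - edge + 1L):nt)] <- FALSE
  }
  if (!any(keep)) {
    abort("epoch fully rejected: no retained samples for power", "eegtrp_empty_power")
  }
  p <- rowMeans(x[, keep, drop = FALSE]^2)
  names(p) <- rownames(x)
  p
}

#' Task-related power (TRP)
#'
#' The log-transformed task power minus the log-transformed baseline power,
#' per electrode: `TRP = log(Pow_task) - log(Pow_baseline)` in the
#' configured base (default 10). Positive values mean a power increase
#' during the task relative to the preceding baseline.
#'
#' @param pow_task,pow_baseline powers in uV^2 (scalars or equal-length vectors).
#' @param log_base logarithm base (default 10).
#' @return TRP value(s) in log units.
#' @export
trp <- function(pow_task, pow_baseline, log_base = 10) {
  if (any(pow_task <= 0) || any(pow_baseline <= 0)) {
    abort("TRP undefined for non-positive power", "eegtrp_nonpositive_power")
  }
  (log(pow_task) - log(pow_baseline)) / log(log_base)
}

#' Welch band-integrated power (spectral cross-check)
#'
#' An independent frequency-domain estimate of band power: Hamming-tapered
#' segments with 50% overlap, averaged one-sided periodograms, integrated
#' over the band. Serves as a cross-check of the time-domain
#' [epoch_power()] route (the two agree within ~10% for band-limited
#' signals); the pipeline itself uses the time-domain mean of squares.
#'
#' @param epoch an `eeg_epoch` (or channels x time matrix).
#' @param band `"theta"`, `"alpha"`, `"beta"` or a `c(low, high)` pair.
#' @param segment_s Welch segment length in seconds (default 4).
#' @param fs sampling rate, required for matrix input.
#' @return Named numeric vector of band powers (uV^2) per electrode.
#' @export
psd_band_power <- function(epoch, band, segment_s = 4, fs = NULL) {
  if (inherits(epoch, "eeg_epoch")) {
    x <- epoch$samples
    fs <- epoch$fs
  } else {
    x <- epoch
    if (is.null(fs)) abort("fs required for matrix input", "eegtrp_bad_fs")
  }
  edges <- if (is.character(band)) {
    if (!band %in% names(EEG_BANDS)) {
      abort(sprintf("unknown band '%s'", band), "eegtrp_unknown_band")
    }
    EEG_BANDS[[band]]
  } else band
  nseg <- round(segment_s * fs)
  nt <- ncol(x)
  if (nt < nseg) abort("epoch shorter than one Welch segment", "eegtrp_signal_too_short")
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  starts <- seq(1L, nt - nseg + 1L, by = max(1L, nseg %/% 2L))
  freqs <- (0:(nseg - 1)) * fs / nseg
  half <- 2:(floor(nseg / 2) + 1)               # positive frequencies
  inband <- half[freqs[half] >= edges[1] & freqs[half] <= edges[2]]
  scale <- 1 / (fs * sum(w^2))
  out <- apply(x, 1, function(ch) {
    psd <- rowMeans(vapply(starts, function(s) {
      seg <- ch[s:(s + nseg - 1L)]
      seg <- (seg - mean(seg)) * w
      (Mod(stats::fft(seg))^2 * scale)[seq_len(nseg)]
    }, numeric(nseg)))
    2 * sum(psd[inband]) * fs / nseg            # one-sided, times df
  })
  names(out) <- rownames(x)
  out
}

#' Band powers for a session's epochs
#'
#' Runs per-epoch artifact rejection (subject threshold + the 100 uV
#' absolute limit), band-pass filters each epoch into the requested bands,
#' and computes per-electrode retained-sample power. One row per
#' (epoch, band, electrode).
#'
#' @param epochs list of `eeg_epoch` (from [segment_session()]).
#' @param bands named list of band edges (default [EEG_BANDS]).
#' @param abs_limit_uV absolute rejection limit (default 100 uV).
#' @param reject if FALSE, skip amplitude rejection (all samples retained).
#' @return List with `powers` (data frame: subject, condition, role,
#'   task_index, band, electrode, pow) and `rejection` (data frame of
#'   per-epoch thresholds and pct_bad).
#' @export
session_band_powers <- function(epochs, bands = EEG_BANDS, abs_limit_uV = 100,
                                reject = TRUE) {
  pow_rows <- list()
  rej_rows <- list()
  for (ep in epochs) {
    if (reject) {
      thr <- subject_threshold(ep)
      rj <- mark_bad_windows(ep, thr, abs_limit_uV = abs_limit_uV)
      mask <- rj$mask
    } else {
      thr <- NA_real_
      rj <- list(threshold_effective_uV = NA_real_, pct_bad = 0)
      mask <- NULL
    }
    rej_rows[[length(rej_rows) + 1L]] <- data.frame(
      subject = ep$subject_id, condition = ep$condition, role = ep$role,
      task_index = ep$task_index, threshold_subject_uV = thr,
      threshold_effective_uV = rj$threshold_effective_uV, pct_bad = rj$pct_bad,
      stringsAsFactors = FALSE)
    for (b in names(bands)) {
      fe <- band_filter(ep, bands[[b]])
      p <- epoch_power(fe, mask = mask)
      pow_rows[[length(pow_rows) + 1L]] <- data.frame(
        subject = ep$subject_id, condition = ep$condition, role = ep$role,
        task_index = ep$task_index, band = b,
        electrode = names(p), pow = as.numeric(p),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  list(powers = do.call(rbind, pow_rows), rejection = do.call(rbind, rej_rows))
}

#' Assemble the long-format TRP analysis table
#'
#' Joins each task-segment power with the power of the baseline recorded
#' immediately before that task (same subject, task and band/electrode) and
#' computes TRP, attaching hemisphere and cortical-area factors from the
#' montage. One row per
#' (subject, projection, segment, band, electrode).
#'
#' @param powers band-power data frame from [session_band_powers()]
#'   (possibly row-bound over a cohort).
#' @param montage an `eeg_montage`.
#' @param log_base TRP logarithm base (default 10).
#' @return Data frame with columns subject, projection, segment, band,
#'   electrode, hemisphere, area, trp.
#' @export
build_trp_table <- function(powers, montage = default_montage(), log_base = 10) {
  task <- powers[powers$role %in% c("seg1", "seg2"), ]
  base <- powers[powers$role == "baseline", ]
  key <- function(d) paste(d$subject, d$task_index, d$band, d$electrode, sep = "\r")
  bmap <- stats::setNames(base$pow, key(base))
  bp <- bmap[key(task)]
  if (anyNA(bp)) {
    abort("missing pre-task baseline power for some task epochs",
          "eegtrp_missing_baseline")
  }
  out <- data.frame(
    subject = task$subject,
    projection = task$condition,
    segment = task$role,
    band = task$band,
    electrode = task$electrode,
    hemisphere = unname(montage$hemisphere_of[task$electrode]),
    area = unname(montage$area_of[task$electrode]),
    trp = trp(task$pow, as.numeric(bp), log_base = log_base),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$subject, out$projection, out$segment, out$band,
            match(out$electrode, montage$electrodes)), , drop = FALSE]
}
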