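#' BSS-CCA parameters
#'
#' Windowed blind source separation by canonical correlation analysis:
#' within each sliding window the canonical correlation between the
#' multichannel signal and its one-sample-lagged copy orders sources by
#' lag-1 autocorrelation; EMG-like (low-autocorrelation, broadband) sources
#' are removed. Defaults follow the study pipeline: 2.5 s windows shifted
#' by 1.2 s, removing the 4 least-correlated of the 14 sources.
#'
#' @param window_s window length in seconds.
#' @param shift_s window shift in seconds.
#' @param k_remove number of least-correlated sources to zero per window.
#' @param lag_samples lag used for the delayed copy (samples).
#' @return An object of class `cca_spec`.
#' @export
cca_spec <- function(window_s = 2.5, shift_s = 1.2, k_remove = 4, lag_samples = 1) {
  if (shift_s > window_s) abort("shift must not exceed the window length", "eegtrp_bad_cca_spec")
  if (k_remove < 0) abort("k_remove must be >= 0", "eegtrp_bad_cca_spec")
  structure(list(window_s = window_s, shift_s = shift_s,
                 k_remove = as.integer(k_remove),
                 lag_samples = as.integer(lag_samples)),
            class = "cca_spec")
}

# Symmetric inverse square root with ridge regularisation for (near-)singular
# window covariances.
inv_sqrt_sym <- function(C, ridge_warn = TRUE) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (any(e$values < tol)) {
    if (ridge_warn) warn_classed("rank-deficient window covariance; regularizing",
                                 "eegtrp_rank_deficient")
    ridge <- max(e$values) * 1e-8 + 1e-12
    e$values <- e$values + ridge
  }
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

# Canonical decomposition of one window against its lagged copy.
# X: channels x time (mean-centred rows expected by the caller).
# Returns sources (channels x time, ordered by canonical correlation
# descending), the correlations, and the mixing matrix A with X = A %*% S.
# The lagged halves are centred separately so the canonical properties
# (diagonal cross-correlation, mutually uncorrelated within-set variates)
# hold exactly on the window.
cca_decompose <- function(X, lag = 1L) {
  nt <- ncol(X)
  X1 <- X[, 1:(nt - lag), drop = FALSE]
  X2 <- X[, (1 + lag):nt, drop = FALSE]
  X1 <- X1 - rowMeans(X1)
  X2 <- X2 - rowMeans(X2)
  n <- ncol(X1)
  Cxx <- tcrossprod(X1) / (n - 1)
  Cyy <- tcrossprod(X2) / (n - 1)
  Cxy <- tcrossprod(X1, X2) / (n - 1)
  Wx <- inv_sqrt_sym(Cxx)
  Wy <- inv_sqrt_sym(Cyy)
  K <- Wx %*% Cxy %*% Wy
  sv <- svd(K)
  U <- Wx %*% sv$u                 # unmixing: S = t(U) %*% X
  S <- t(U) %*% X
  A <- solve(t(U))                 # mixing: X = A %*% S
  list(sources = S, correlations = sv$d, mixing = A, unmixing = U)
}

#' Remove EMG-like components by windowed BSS-CCA
#'
#' Slides windows of `spec$window_s` seconds (shift `spec$shift_s`) over the
#' recording. In each window the channels are mean-centred, sources are
#' obtained by CCA between the window and its lag-1 copy, the `k_remove`
#' sources with the lowest canonical correlation (lowest lag-1
#' autocorrelation, the EMG signature) are zeroed, and the window is
#' reconstructed through the mixing matrix. Overlapping reconstructions are
#' blended with a linear crossfade. A trailing remainder of at least 0.5 s
#' is processed as its own shorter window; anything shorter passes through
#' unfiltered.
#'
#' @param recording an `eeg_recording`.
#' @param spec a [cca_spec()].
#' @return The denoised recording, same shape.
#' @export
bss_cca_denoise <- function(recording, spec = cca_spec()) {
  nch <- nrow(recording$samples)
  nt <- ncol(recording$samples)
  if (spec$k_remove >= nch) {
    abort("k_remove must be smaller than the channel count", "eegtrp_bad_cca_spec")
  }
  if (spec$k_remove == 0L) return(recording)
  W <- round(spec$window_s * recording$fs)
  shift <- max(1L, round(spec$shift_s * recording$fs))
  if (W <= nch) abort("window too short for the channel count", "eegtrp_bad_cca_spec")
  if (nt < W) abort("recording shorter than one CCA window", "eegtrp_signal_too_short")
  min_tail <- round(0.5 * recording$fs)

  starts <- seq(1L, nt - W + 1L, by = shift)
  covered_end <- starts[length(starts)] + W - 1L
  tail_len <- nt - covered_end
  windows <- lapply(starts, function(s) c(s, s + W - 1L))
  if (tail_len >= min_tail) {
    windows <- c(windows, list(c(covered_end + 1L, nt)))
  }

  acc <- matrix(0, nch, nt)
  wsum <- rep(0, nt)
  overlap <- max(1L, W - shift)
  for (win in windows) {
    idx <- win[1]:win[2]
    X <- recording$samples[, idx, drop = FALSE]
    mu <- rowMeans(X)
    Xc <- X - mu
    dec <- cca_decompose(Xc, lag = spec$lag_samples)
    S <- dec$sources
    keep <- seq_len(nch - spec$k_remove)
    Xhat <- dec$mixing[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + mu
    # trapezoid weight: linear crossfade over the overlap at interior seams
    L <- length(idx)
    w <- rep(1, L)
    ramp <- min(overlap, L)
    if (win[1] > 1L) w[1:ramp] <- seq(1 / ramp, 1, length.out = ramp)
    if (win[2] < nt) w[(L - ramp + 1L):L] <- seq(1, 1 / ramp, length.out = ramp)
    acc[, idx] <- acc[, idx] + sweep(Xhat, 2, w, `*`)
    wsum[idx] <- wsum[idx] + w
  }

  out <- recording
  uncovered <- wsum == 0
  if (any(uncovered)) {
    acc[, uncovered] <- recording$samples[, uncovered]
    wsum[uncovered] <- 1
  }
  out$samples <- sweep(acc, 2, wsum, `/`)
  rownames(out$samples) <- recording$channel_labels
  out
}
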