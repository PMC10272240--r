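test_that("first-order high-pass removes DC and passes in-band sinusoids", {
  # constant 4200 uV: settled output is essentially zero
  rec <- new_recording(matrix(4200, 14, FS * 60), fs = FS)
  hp <- highpass_dc_remove(rec)
  expect_lt(abs(mean(hp$samples[, (50 * FS):(60 * FS)])), 1)

  # zero in, zero out
  z <- new_recording(matrix(0, 14, FS * 10), fs = FS)
  expect_true(all(highpass_dc_remove(z)$samples == 0))

  # 10 Hz sine: analytic first-order gain |H| = f/sqrt(f^2 + fc^2)
  t <- (0:(FS * 30 - 1)) / FS
  s <- sin(2 * pi * 10 * t)
  rec2 <- new_recording(matrix(rep(s, 14), 14, byrow = TRUE), fs = FS)
  out <- highpass_dc_remove(rec2)$samples[1, (10 * FS):(30 * FS)]
  gain <- max(abs(out))
  expect_lt(abs(gain - 10 / sqrt(10^2 + 0.16^2)), 0.001)

  expect_error(highpass_dc_remove(rec, fc = -1), class = "eegtrp_bad_cutoff")
})

test_that("FIR band-pass matches its frequency-response oracle", {
  t <- (0:(FS * 30 - 1)) / FS
  mk <- function(f) new_recording(matrix(rep(sin(2 * pi * f * t), 14), 14,
                                         byrow = TRUE), fs = FS)
  # 10 Hz is deep in the 4-45 passband
  y10 <- fir_bandpass(mk(10), 4, 45)$samples[1, (5 * FS):(25 * FS)]
  expect_lt(abs(max(abs(y10)) - 1), 0.02)
  # 1 Hz is in the stopband
  y1 <- fir_bandpass(mk(1), 4, 45)$samples[1, (5 * FS):(25 * FS)]
  expect_lte(sqrt(mean(y1^2)) / sqrt(0.5), 0.1)
  # taps are symmetric (linear phase)
  taps <- eegtrp:::fir_design_bandpass(4, 45, FS)
  expect_equal(taps, rev(taps), tolerance = 1e-12)
  # signal shorter than the filter is an error
  tiny <- new_recording(matrix(0, 14, 16), fs = FS)
  expect_error(fir_bandpass(tiny, 4, 45), class = "eegtrp_signal_too_short")
})

test_that("filtering is channel-wise: permuting channels commutes with filtering", {
  set.seed(3)
  rec <- new_recording(matrix(rnorm(14 * FS * 10), 14), fs = FS)
  perm <- sample(14)
  f1 <- fir_bandpass(rec, 4, 45)$samples[perm, ]
  rec_p <- rec
  rec_p$samples <- rec$samples[perm, ]
  f2 <- fir_bandpass(rec_p, 4, 45)$samples
  expect_equal(unname(f1), unname(f2), tolerance = 1e-12)
})

test_that("CCA sources are uncorrelated and ordered by lag-1 autocorrelation", {
  # mixture of AR(1) sources with well-separated autocorrelations
  set.seed(8)
  phis <- c(0.95, 0.8, 0.6, 0.3, 0)
  nt <- 4000
  S_true <- t(sapply(phis, function(ph) {
    as.numeric(stats::filter(rnorm(nt), ph, method = "recursive"))
  }))
  A_mix <- matrix(rnorm(25), 5)
  X <- A_mix %*% S_true
  Xc <- X - rowMeans(X)
  dec <- eegtrp:::cca_decompose(Xc, lag = 1L)
  # canonical correlations non-increasing (sort contract)
  expect_true(all(diff(dec$correlations) <= 1e-12))
  # within-set canonical variates are mutually uncorrelated
  X1c <- Xc[, -nt]; X1c <- X1c - rowMeans(X1c)
  V1 <- t(dec$unmixing) %*% X1c
  cc <- stats::cor(t(V1))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
  # recovered source order tracks the lag-1 autocorrelation order:
  # the k lowest-canonical-correlation sources are the k least
  # autocorrelated (exhaustive over k)
  ac <- apply(dec$sources, 1, function(s) stats::cor(s[-length(s)], s[-1]))
  for (k in 1:4) {
    removed <- tail(seq_along(ac), k)
    expect_setequal(removed, order(ac)[seq_len(k)])
  }
  # mixing inverts unmixing: X = A %*% S
  expect_equal(dec$mixing %*% dec$sources, Xc, tolerance = 1e-8)
  # agreement with stats::cancor on the same window
  ref <- stats::cancor(t(Xc[, -nt]), t(Xc[, -1]))
  expect_equal(dec$correlations, ref$cor, tolerance = 1e-8)
})

test_that("BSS-CCA removes an EMG burst but preserves alpha elsewhere", {
  # volume conduction: 8 alpha sources mixed into 14 channels plus weak
  # autocorrelated background noise, so the EMG burst is unambiguously the
  # least-autocorrelated source in its windows
  rec <- mixed_alpha_recording(seed = 30)
  inj <- inject_artifacts(rec, "emg_burst",
                          params = list(n_bursts = 1, burst_rms_uV = 30,
                                        burst_channels = "T7"), seed = 3)
  den <- bss_cca_denoise(inj$recording, cca_spec())
  row <- inj$artifact_log[1, ]
  ch <- match("T7", rec$channel_labels)
  idx <- round(row$onset_s * FS) + seq_len(FS)
  reduction <- 1 - band_energy(den$samples[ch, idx], 20, 45) /
    band_energy(inj$recording$samples[ch, idx], 20, 45)
  expect_gte(reduction, 0.5)
  # alpha power away from the burst within 10%
  far <- setdiff(seq(2 * FS, 18 * FS), seq(min(idx) - 2 * FS, max(idx) + 2 * FS))
  for (c2 in c(1, 5, 10)) {
    ratio <- band_energy(den$samples[c2, far], 8, 12) /
      band_energy(inj$recording$samples[c2, far], 8, 12)
    expect_lt(abs(ratio - 1), 0.10)
  }
})

test_that("BSS-CCA with k_remove = 0 is the identity and seams are smooth", {
  set.seed(4)
  rec <- new_recording(matrix(rnorm(14 * FS * 10), 14), fs = FS)
  expect_identical(bss_cca_denoise(rec, cca_spec(k_remove = 0))$samples,
                   rec$samples)

  # smooth input: no discontinuity artifacts at window seams
  base <- sapply(1:14, function(i) synth_band_oscillation("alpha", 12, FS, 10,
                                                          seed = 20 + i))
  smooth_rec <- new_recording(t(base), fs = FS)
  den <- bss_cca_denoise(smooth_rec, cca_spec())
  jumps <- abs(diff(den$samples[1, ]))
  shift <- round(1.2 * FS)
  seam_idx <- seq(shift, ncol(den$samples) - 1, by = shift)
  expect_lte(max(jumps[seam_idx]), 5 * stats::median(jumps))

  expect_error(bss_cca_denoise(rec, cca_spec(k_remove = 14)),
               class = "eegtrp_bad_cca_spec")
})
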