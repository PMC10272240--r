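test_that("band filters match their frequency-response oracle", {
  ep10 <- sine_epoch(10, 1, 30)
  # 10 Hz through the alpha filter: passband, amplitude preserved
  ya <- band_filter(ep10, "alpha")$samples[1, (5 * FS):(25 * FS)]
  expect_lt(abs(max(abs(ya)) - 1), 0.02)
  # 10 Hz through the beta filter: stopband
  yb <- band_filter(ep10, "beta")$samples[1, (5 * FS):(25 * FS)]
  expect_lte(sqrt(mean(yb^2)) / sqrt(0.5), 0.1)
  # zero in, zero out
  z <- sine_epoch(10, 0, 30)
  expect_true(all(band_filter(z, "theta")$samples == 0))
  expect_error(band_filter(sine_epoch(10, 1, 0.5), "theta"),
               class = "eegtrp_signal_too_short")
})

test_that("epoch power equals the analytic mean square of a sinusoid", {
  ep <- sine_epoch(10, 2, 30)
  fe <- band_filter(ep, "alpha")
  p <- epoch_power(fe)
  expect_lt(abs(p[[1]] / 2 - 1), 0.01)   # a^2/2 with a = 2
  # all-zero epoch has zero power
  expect_true(all(epoch_power(band_filter(sine_epoch(10, 0, 30), "alpha")) == 0))
})

test_that("masked samples are excluded from the power average", {
  nt <- 20 * FS
  x <- matrix(0, 14, nt)
  x[, (nt / 2 + 1):nt] <- 3          # all energy in the second half
  mask <- rep(c(TRUE, FALSE), each = nt / 2)
  p <- epoch_power(x, mask = mask, edge_samples = 0)
  expect_equal(unname(p), rep(0, 14))  # retained half only
  p2 <- epoch_power(x, mask = !mask, edge_samples = 0)
  expect_equal(unname(p2), rep(9, 14))
  expect_error(epoch_power(x, mask = rep(FALSE, nt), edge_samples = 0),
               class = "eegtrp_empty_power")
})

test_that("trp is the base-10 log power ratio with a sign convention", {
  expect_equal(trp(5, 5), 0)
  expect_equal(trp(10, 1), 1)
  # task amplitude 10 vs baseline amplitude 5 => TRP = log10(4)
  pt <- epoch_power(band_filter(sine_epoch(10, 10, 30), "alpha"))
  pb <- epoch_power(band_filter(sine_epoch(10, 5, 30), "alpha"))
  expect_lt(abs(trp(pt[[1]], pb[[1]]) - log10(4)), 0.01 * log10(4))
  expect_error(trp(0, 1), class = "eegtrp_nonpositive_power")
  # scale equivariance: common scaling cancels
  expect_equal(trp(3 * 7, 3 * 2), trp(7, 2), tolerance = 1e-12)
})

test_that("band decomposition separates a per-band composite within 5%", {
  parts <- list(theta = synth_band_oscillation("theta", 60, FS, 6, seed = 41),
                alpha = synth_band_oscillation("alpha", 60, FS, 10, seed = 42),
                beta = synth_band_oscillation("beta", 60, FS, 4, seed = 43))
  comp <- Reduce(`+`, parts)
  as_ep <- function(x) new_epoch(matrix(rep(x, 14), 14, byrow = TRUE), FS,
                                 "S01", "isometric", "seg1", 1L, 0, 60)
  # each band's measured power in the composite matches the same band's
  # measured power for the single component alone (cross-band leakage < 5%)
  for (b in names(parts)) {
    p_comp <- epoch_power(band_filter(as_ep(comp), b))[[1]]
    p_single <- epoch_power(band_filter(as_ep(parts[[b]]), b))[[1]]
    expect_lt(abs(p_comp / p_single - 1), 0.05)
  }
})

test_that("Welch band power cross-checks the time-domain route within 10%", {
  # in-band sinusoid: both routes near a^2/2
  ep <- sine_epoch(10, 2, 30)
  fe <- band_filter(ep, "alpha")
  p_time <- epoch_power(fe)[[1]]
  p_welch <- psd_band_power(ep, "alpha")[[1]]
  expect_lt(abs(p_welch / p_time - 1), 0.10)
  # band-limited noise oscillation
  x <- synth_band_oscillation("beta", 60, FS, 8, seed = 61)
  ep2 <- new_epoch(matrix(rep(x, 14), 14, byrow = TRUE), FS, "S01",
                   "isometric", "seg1", 1L, 0, 60)
  p_t2 <- epoch_power(band_filter(ep2, "beta"))[[1]]
  p_w2 <- psd_band_power(ep2, "beta")[[1]]
  expect_lt(abs(p_w2 / p_t2 - 1), 0.10)
})

test_that("the TRP table has the factorial shape with montage factors attached", {
  # tiny synthetic power table: 2 subjects x 2 conditions x 2 segments x
  # 3 bands x 14 electrodes
  m <- default_montage()
  grid <- expand.grid(subject = c("S01", "S02"),
                      condition = c("isometric", "orthographic"),
                      role = c("baseline", "seg1", "seg2"),
                      band = names(EEG_BANDS), electrode = m$electrodes,
                      stringsAsFactors = FALSE)
  grid$task_index <- ifelse(grid$condition == "isometric", 1L, 2L)
  set.seed(44)
  grid$pow <- runif(nrow(grid), 1, 10)
  tab <- build_trp_table(grid)
  expect_equal(nrow(tab), 2 * 2 * 2 * 3 * 14)
  f4 <- tab[tab$electrode == "F4", ][1, ]
  expect_equal(f4$hemisphere, "RH")
  expect_equal(f4$area, "FA")
  # TRP values equal the hand-computed log ratio
  one <- tab[1, ]
  pt <- grid$pow[grid$subject == one$subject & grid$condition == one$projection &
                   grid$role == one$segment & grid$band == one$band &
                   grid$electrode == one$electrode]
  pb <- grid$pow[grid$subject == one$subject & grid$condition == one$projection &
                   grid$role == "baseline" & grid$band == one$band &
                   grid$electrode == one$electrode]
  expect_equal(one$trp, log10(pt / pb), tolerance = 1e-12)
  # missing baseline partner is an error
  expect_error(build_trp_table(grid[grid$role != "baseline", ]),
               class = "eegtrp_missing_baseline")
})
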