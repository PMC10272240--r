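#' Cohort specification for the synthetic-EEG simulator
#'
#' Defines the simulated study conditions: cohort size, segment durations,
#' per-band baseline oscillation amplitudes, task/baseline amplitude gains,
#' factor effect offsets, and the background-noise model. Defaults emulate
#' the study design: 18 analysed subjects, 20 s pre-task baselines, two
#' tasks per session (one per projection condition) with counterbalanced
#' order, and segment durations set to one tenth of the study's median
#' completion times (seg1 3.2/7.15 s, seg2 86.1/90.4 s for
#' isometric/orthographic) so that a full cohort stays desk-scale.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param baseline_s baseline duration in seconds (default 20).
#' @param seg1_s,seg2_s named `c(isometric=, orthographic=)` segment durations.
#' @param baseline_amplitudes_uV named per-band oscillation amplitudes
#'   (microvolts) during baselines. Alpha dominates resting EEG, theta and
#'   beta are weaker.
#' @param gains nested list `gains[[band]][[condition]]`: task/baseline
#'   amplitude gain, either a scalar or `c(seg1=, seg2=)`. Default all 1
#'   (null cohort).
#' @param effect_spec named list of additive TRP offsets in log10-power
#'   units applied on top of `gains`: `projection` (added for orthographic
#'   task epochs), `hemisphere` (added over LH), `area` (added over FA);
#'   each is a named per-band vector. Default all zero.
#' @param noise_amplitude_uV RMS of the 1/f background (default 5).
#' @param noise_exponent chi of the 1/f^chi background (default 1).
#' @param oscillation_mode `"noise"` (band-pass filtered noise, realistic
#'   spectrum) or `"sine"` (pure sinusoids, for analytic tests).
#' @param fs sampling rate (default 128 Hz).
#' @param gap_s silence between consecutive experiment phases (default 1 s).
#' @param seed cohort seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 18,
                        baseline_s = 20,
                        seg1_s = c(isometric = 3.2, orthographic = 7.15),
                        seg2_s = c(isometric = 86.1, orthographic = 90.4),
                        baseline_amplitudes_uV = c(theta = 6, alpha = 10, beta = 4),
                        gains = NULL,
                        effect_spec = NULL,
                        noise_amplitude_uV = 5,
                        noise_exponent = 1,
                        oscillation_mode = c("noise", "sine"),
                        fs = 128,
                        gap_s = 1,
                        seed = 1L) {
  if (!is_count(n_subjects) || n_subjects < 2) {
    abort("n_subjects must be an integer >= 2", "eegtrp_bad_spec")
  }
  if (baseline_s <= 0 || any(seg1_s <= 0) || any(seg2_s <= 0)) {
    abort("durations must be positive", "eegtrp_bad_spec")
  }
  bands <- names(EEG_BANDS)
  if (is.null(gains)) gains <- list()
  for (b in bands) {
    if (is.null(gains[[b]])) gains[[b]] <- list()
    for (cond in c("isometric", "orthographic")) {
      g <- gains[[b]][[cond]]
      if (is.null(g)) g <- 1
      if (length(g) == 1) g <- c(seg1 = unname(g), seg2 = unname(g))
      if (any(g <= 0)) abort("gains must be positive", "eegtrp_bad_spec")
      gains[[b]][[cond]] <- g
    }
  }
  zero <- stats::setNames(rep(0, length(bands)), bands)
  es <- list(projection = zero, hemisphere = zero, area = zero)
  for (f in names(effect_spec %||% list())) {
    v <- zero
    v[names(effect_spec[[f]])] <- effect_spec[[f]]
    es[[f]] <- v
  }
  structure(
    list(n_subjects = as.integer(n_subjects), baseline_s = baseline_s,
         seg1_s = seg1_s, seg2_s = seg2_s,
         baseline_amplitudes_uV = baseline_amplitudes_uV,
         gains = gains, effect_spec = es,
         noise_amplitude_uV = noise_amplitude_uV,
         noise_exponent = noise_exponent,
         oscillation_mode = match.arg(oscillation_mode),
         fs = fs, gap_s = gap_s, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Band-limited oscillation
#'
#' A zero-mean single-channel signal whose spectral power is concentrated in
#' the named band, scaled so its RMS equals `amplitude_uV / sqrt(2)` (the
#' RMS of a sinusoid of amplitude `amplitude_uV`). `mode = "noise"` filters
#' white noise into the band (realistic EEG-like spectrum);
#' `mode = "sine"` emits a pure sinusoid at the band centre.
#'
#' @param band `"theta"`, `"alpha"` or `"beta"`, or a `c(low, high)` pair.
#' @param duration_s,fs length and sampling rate.
#' @param amplitude_uV amplitude scaling; 0 gives an all-zero signal.
#' @param seed RNG seed (noise mode) / phase seed (sine mode).
#' @param mode `"noise"` or `"sine"`.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
synth_band_oscillation <- function(band, duration_s, fs = 128, amplitude_uV = 10,
                                   seed = 1L, mode = c("noise", "sine")) {
  mode <- match.arg(mode)
  if (is.character(band)) {
    if (!band %in% names(EEG_BANDS)) {
      abort(sprintf("unknown band '%s'", band), "eegtrp_unknown_band")
    }
    edges <- EEG_BANDS[[band]]
  } else edges <- band
  nt <- round(duration_s * fs)
  if (amplitude_uV == 0) return(rep(0, nt))
  target_rms <- amplitude_uV / sqrt(2)
  if (mode == "sine") {
    f0 <- mean(edges)
    phase <- with_seed(seed, stats::runif(1, 0, 2 * pi))
    return(amplitude_uV * sin(2 * pi * f0 * (0:(nt - 1)) / fs + phase))
  }
  taps <- fir_design_bandpass(edges[1], edges[2], fs)
  pad <- length(taps)
  if (nt + 2 * pad < length(taps)) {
    abort("duration too short for the band filter warm-up", "eegtrp_signal_too_short")
  }
  x <- with_seed(seed, stats::rnorm(nt + 2 * pad))
  y <- apply_fir_zerophase(x, taps)[(pad + 1):(pad + nt)]
  y <- y - mean(y)
  y / rms(y) * target_rms
}

# 1/f^chi background noise via FFT spectral shaping, scaled to a target RMS.
synth_pink_noise <- function(nt, fs, amplitude_rms, chi = 1, seed = 1L) {
  if (amplitude_rms == 0) return(rep(0, nt))
  x <- with_seed(seed, stats::rnorm(nt))
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = nt + 1)[1:nt]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  scale <- ifelse(f < fs / nt, 0, f^(-chi / 2))
  y <- Re(stats::fft(X * scale, inverse = TRUE)) / nt
  y <- y - mean(y)
  y / rms(y) * amplitude_rms
}

# Net amplitude gain for a task epoch at one electrode:
# base condition/segment gain times the factor offsets (TRP log10-power
# offset d maps to amplitude factor 10^(d/2), since power ~ amplitude^2).
net_gain <- function(spec, band, condition, segment, electrode, montage) {
  g <- spec$gains[[band]][[condition]][[segment]]
  d <- 0
  if (condition == "orthographic") d <- d + spec$effect_spec$projection[[band]]
  if (montage$hemisphere_of[[electrode]] == "LH") d <- d + spec$effect_spec$hemisphere[[band]]
  if (montage$area_of[[electrode]] == "FA") d <- d + spec$effect_spec$area[[band]]
  g * 10^(d / 2)
}

#' Simulate one experiment session
#'
#' Builds a continuous 14-channel recording laid out as
#' baseline 1, task 1 (seg1 + seg2), baseline 2, task 2 (seg1 + seg2), with
#' short gaps between phases, together with its event log and the ground
#' truth of applied gains. Each channel is the sum of a 1/f background and
#' one band-limited oscillation per band whose amplitude is the baseline
#' amplitude during baselines and the gained amplitude during task epochs.
#' Expected TRP per (band, condition, segment, electrode) is
#' `2 * log10(gain)`.
#'
#' @param spec a [cohort_spec()].
#' @param subject_id subject identifier.
#' @param seed session seed.
#' @param order `"AB"` (isometric first) or `"BA"`.
#' @param montage montage (default [default_montage()]).
#' @return List with `recording`, `events` and `ground_truth` (data frame:
#'   band, condition, segment, electrode, gain, expected_trp; plus
#'   attributes `baseline_amplitudes` and `artifact_log`).
#' @export
synth_subject_session <- function(spec, subject_id = "S01", seed = spec$seed,
                                  order = c("AB", "BA"),
                                  montage = default_montage()) {
  order <- match.arg(order)
  conds <- if (order == "AB") c("isometric", "orthographic") else c("orthographic", "isometric")
  fs <- spec$fs
  gap <- spec$gap_s

  # timeline
  phases <- list()
  t <- 0
  ev <- list()
  add_ev <- function(time, marker, condition, task_index) {
    ev[[length(ev) + 1L]] <<- data.frame(time_s = time, marker = marker,
                                         condition = condition,
                                         task_index = task_index,
                                         stringsAsFactors = FALSE)
  }
  for (k in 1:2) {
    cond <- conds[k]
    add_ev(t, "baseline_start", cond, k)
    phases[[length(phases) + 1L]] <- list(role = "baseline", condition = cond,
                                          task = k, t0 = t, t1 = t + spec$baseline_s)
    t <- t + spec$baseline_s
    add_ev(t, "baseline_end", cond, k)
    t <- t + gap
    add_ev(t, "drawing_shown", cond, k)
    phases[[length(phases) + 1L]] <- list(role = "seg1", condition = cond,
                                          task = k, t0 = t, t1 = t + spec$seg1_s[[cond]])
    t <- t + spec$seg1_s[[cond]]
    add_ev(t, "first_sketch_element", cond, k)
    phases[[length(phases) + 1L]] <- list(role = "seg2", condition = cond,
                                          task = k, t0 = t, t1 = t + spec$seg2_s[[cond]])
    t <- t + spec$seg2_s[[cond]]
    add_ev(t, "task_end", cond, k)
    t <- t + gap
  }
  total_s <- t
  nt <- round(total_s * fs)
  events <- do.call(rbind, ev)

  electrodes <- montage$electrodes
  nch <- length(electrodes)
  samples <- matrix(0, nch, nt)
  bands <- names(EEG_BANDS)

  # envelope per (band, electrode): amplitude multiplier per sample
  for (ci in seq_len(nch)) {
    el <- electrodes[ci]
    ch_seed <- derive_seed(seed, ci)
    chan <- synth_pink_noise(nt, fs, spec$noise_amplitude_uV,
                             chi = spec$noise_exponent, seed = ch_seed)
    for (bi in seq_along(bands)) {
      b <- bands[bi]
      osc <- synth_band_oscillation(b, nt / fs, fs,
                                    amplitude_uV = spec$baseline_amplitudes_uV[[b]],
                                    seed = derive_seed(ch_seed, 100L * bi),
                                    mode = spec$oscillation_mode)
      envel <- rep(0, nt)
      for (ph in phases) {
        i0 <- round(ph$t0 * fs) + 1L
        i1 <- round(ph$t1 * fs)
        mult <- if (ph$role == "baseline") 1 else {
          net_gain(spec, b, ph$condition, ph$role, el, montage)
        }
        envel[i0:i1] <- mult
      }
      # gaps keep baseline-level oscillation so transitions stay mild
      envel[envel == 0] <- 1
      samples[ci, ] <- samples[ci, ] + osc * envel
    }
    samples[ci, ] <- samples[ci, ] + chan
  }

  gt <- expand.grid(band = bands, condition = conds, segment = c("seg1", "seg2"),
                    electrode = electrodes, stringsAsFactors = FALSE)
  gt$gain <- mapply(function(b, cond, seg, el) net_gain(spec, b, cond, seg, el, montage),
                    gt$band, gt$condition, gt$segment, gt$electrode)
  gt$expected_trp <- 2 * log10(gt$gain)
  attr(gt, "baseline_amplitudes") <- spec$baseline_amplitudes_uV
  attr(gt, "artifact_log") <- data.frame(kind = character(), channel = character(),
                                         onset_s = numeric(), duration_s = numeric(),
                                         peak_uV = numeric())

  rec <- new_recording(samples, fs = fs, channel_labels = electrodes,
                       subject_id = subject_id)
  list(recording = rec, events = load_events(events), ground_truth = gt)
}

#' Inject artifacts into a recording
#'
#' Adds the artifact classes the cleaning stages target: a constant DC
#' offset on all channels (amplifier offset), brief high-amplitude spikes
#' on single channels, and band-limited 20-45 Hz EMG bursts. Every
#' injection is logged exactly.
#'
#' @param recording an `eeg_recording`.
#' @param kinds subset of `c("dc_offset", "spike", "emg_burst")`.
#' @param params list of optional parameters: `dc_uV` (default 4200),
#'   `n_spikes` (default 3), `spike_peak_uV` (default 150),
#'   `spike_duration_s` (default 1/recording fs, i.e. one sample),
#'   `n_bursts` (default 2), `burst_rms_uV` (default 30),
#'   `burst_duration_s` (default 1), `burst_channels` (labels; default random).
#' @param seed RNG seed for placement.
#' @return List with the modified `recording` and the `artifact_log`
#'   data frame (kind, channel, onset_s, duration_s, peak_uV).
#' @export
inject_artifacts <- function(recording, kinds = character(), params = list(),
                             seed = 1L) {
  if (length(kinds) > 0) {
    kinds <- match.arg(kinds, c("dc_offset", "spike", "emg_burst"), several.ok = TRUE)
  }
  x <- recording$samples
  fs <- recording$fs
  nt <- ncol(x)
  dur <- nt / fs
  log_rows <- list()
  add_log <- function(kind, channel, onset, duration, peak) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      kind = kind, channel = channel, onset_s = onset,
      duration_s = duration, peak_uV = peak, stringsAsFactors = FALSE)
  }

  with_seed(seed, {
    if ("dc_offset" %in% kinds) {
      dc <- params$dc_uV %||% 4200
      x <- x + dc
      add_log("dc_offset", "all", 0, dur, dc)
    }
    if ("spike" %in% kinds) {
      peak <- params$spike_peak_uV %||% 150
      if (peak <= 0) abort("spike peak must be positive", "eegtrp_undetectable_artifact")
      nsp <- params$n_spikes %||% 3
      sp_dur <- params$spike_duration_s %||% (1 / fs)
      wid <- max(1L, round(sp_dur * fs))
      for (i in seq_len(nsp)) {
        ch <- sample(nrow(x), 1)
        i0 <- sample(nt - wid, 1)
        x[ch, i0:(i0 + wid - 1L)] <- x[ch, i0:(i0 + wid - 1L)] +
          peak * sample(c(-1, 1), 1)
        add_log("spike", recording$channel_labels[ch], (i0 - 1) / fs, wid / fs, peak)
      }
    }
    if ("emg_burst" %in% kinds) {
      nb <- params$n_bursts %||% 2
      b_rms <- params$burst_rms_uV %||% 30
      if (b_rms <= 0) abort("burst amplitude must be positive", "eegtrp_undetectable_artifact")
      b_dur <- params$burst_duration_s %||% 1
      wid <- round(b_dur * fs)
      chans <- params$burst_channels %||% NULL
      for (i in seq_len(nb)) {
        ch <- if (is.null(chans)) sample(nrow(x), 1) else {
          match(chans[(i - 1L) %% length(chans) + 1L], recording$channel_labels)
        }
        i0 <- sample(nt - wid, 1)
        burst <- synth_band_oscillation(c(20, 45), wid / fs, fs,
                                        amplitude_uV = b_rms * sqrt(2),
                                        seed = derive_seed(seed, 7L * i), mode = "noise")
        # taper ends so the burst doesn't add step discontinuities
        ramp <- max(2L, round(0.05 * wid))
        w <- rep(1, wid)
        w[1:ramp] <- seq(0, 1, length.out = ramp)
        w[(wid - ramp + 1L):wid] <- seq(1, 0, length.out = ramp)
        x[ch, i0:(i0 + wid - 1L)] <- x[ch, i0:(i0 + wid - 1L)] + burst * w
        add_log("emg_burst", recording$channel_labels[ch], (i0 - 1) / fs,
                b_dur, max(abs(burst)))
      }
    }
  })

  out <- recording
  out$samples <- x
  alog <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(kind = character(), channel = character(), onset_s = numeric(),
               duration_s = numeric(), peak_uV = numeric())
  list(recording = out, artifact_log = alog)
}

#' Simulate a cohort of experiment sessions
#'
#' Generates `spec$n_subjects` sessions with counterbalanced condition
#' order: the first half of the cohort runs isometric-then-orthographic
#' ("AB"), the second half the reverse, emulating the study's two
#' controlled-order groups. Deterministic given `(spec, spec$seed)`.
#'
#' @param spec a [cohort_spec()].
#' @param montage montage (default [default_montage()]).
#' @return List of per-subject sessions (each as in
#'   [synth_subject_session()]) plus a `ground_truth` cohort data frame.
#' @export
synth_cohort <- function(spec, montage = default_montage()) {
  n <- spec$n_subjects
  orders <- rep(c("AB", "BA"), each = ceiling(n / 2))[1:n]
  sessions <- vector("list", n)
  gt_all <- list()
  for (i in seq_len(n)) {
    sid <- sprintf("S%02d", i)
    ses <- synth_subject_session(spec, subject_id = sid,
                                 seed = derive_seed(spec$seed, i),
                                 order = orders[i], montage = montage)
    sessions[[i]] <- ses
    g <- ses$ground_truth
    g$subject <- sid
    gt_all[[i]] <- g
  }
  list(sessions = sessions, ground_truth = do.call(rbind, gt_all),
       orders = stats::setNames(orders, sprintf("S%02d", seq_len(n))))
}
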