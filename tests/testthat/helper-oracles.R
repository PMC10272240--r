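# Shared fixtures and independent oracles used across test files.

FS <- 128

# Fraction of periodogram power inside [lo, hi] Hz.
band_power_fraction <- function(x, lo, hi, fs = FS) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE, taper = 0,
                          detrend = FALSE)
  sum(sp$spec[sp$freq >= lo & sp$freq <= hi]) / sum(sp$spec)
}

# Band-limited periodogram energy (unnormalised), for before/after ratios.
band_energy <- function(x, lo, hi, fs = FS) {
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE, taper = 0,
                          detrend = FALSE)
  sum(sp$spec[sp$freq >= lo & sp$freq <= hi])
}

# Brute-force sliding-window rejection: explicit loop over every window.
brute_force_rejection <- function(x, threshold_uV, abs_limit_uV = 100,
                                  wlen = FS) {
  nt <- ncol(x)
  thr_eff <- min(threshold_uV, abs_limit_uV)
  a <- abs(x)
  nwin <- nt - wlen + 1L
  bad_win <- logical(nwin)
  for (s in seq_len(nwin)) {
    w <- a[, s:(s + wlen - 1L), drop = FALSE]
    bad_win[s] <- mean(w) > thr_eff || any(w > abs_limit_uV)
  }
  mask <- rep(TRUE, nt)
  for (s in which(bad_win)) mask[s:(s + wlen - 1L)] <- FALSE
  list(mask = mask, pct_bad = 100 * mean(!mask))
}

# Exhaustive signed-rank null: V and two-sided p over all 2^n sign patterns.
brute_force_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Vs <- signs %*% rk
  p <- min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
  list(V = V, p = p)
}

# Parametric one-way repeated-measures ANOVA computed from sums of squares
# (independent of stats::aov), for the ART oracle-equivalence check.
rm_anova_by_hand <- function(y, subject, a) {
  subject <- factor(subject); a <- factor(a)
  grand <- mean(y)
  n_s <- nlevels(subject); n_a <- nlevels(a)
  m_a <- tapply(y, a, mean)
  m_s <- tapply(y, subject, mean)
  ss_a <- n_s * sum((m_a - grand)^2)
  cellm <- tapply(y, list(subject, a), mean)
  ss_err <- sum((cellm - outer(m_s - grand, m_a - grand, `+`) - grand)^2)
  df_a <- n_a - 1
  df_err <- (n_s - 1) * (n_a - 1)
  Fv <- (ss_a / df_a) / (ss_err / df_err)
  list(F = Fv, df1 = df_a, df2 = df_err,
       p = stats::pf(Fv, df_a, df_err, lower.tail = FALSE))
}

# Volume-conducted clean EEG: `n_src` alpha sources mixed into 14 channels
# plus weak AR(1) background noise (autocorrelated, like real EEG drift).
mixed_alpha_recording <- function(duration_s = 20, n_src = 8, seed = 30,
                                  noise_sd = 0.5) {
  set.seed(seed)
  src <- t(sapply(seq_len(n_src), function(i) {
    synth_band_oscillation("alpha", duration_s, FS, 10, seed = seed + i)
  }))
  mix <- matrix(stats::runif(14 * n_src, 0.2, 1), 14, n_src)
  noise <- t(sapply(1:14, function(i) {
    z <- as.numeric(stats::filter(stats::rnorm(duration_s * FS), 0.5,
                                  method = "recursive"))
    z / stats::sd(z) * noise_sd
  }))
  new_recording(mix %*% src + noise, fs = FS)
}

# Small deterministic sinusoid epoch helper.
sine_epoch <- function(freq, amplitude, duration_s, fs = FS, nch = 14,
                       condition = "isometric", role = "seg1") {
  t <- (0:(round(duration_s * fs) - 1)) / fs
  s <- amplitude * sin(2 * pi * freq * t)
  new_epoch(matrix(rep(s, nch), nch, byrow = TRUE), fs, "S01", condition, role,
            1L, 0, duration_s)
}

# A tiny well-formed two-task event log.
tiny_event_log <- function() {
  data.frame(
    time_s = c(0, 20, 21, 25, 50, 51, 71, 72, 76, 100),
    marker = c("baseline_start", "baseline_end", "drawing_shown",
               "first_sketch_element", "task_end", "baseline_start",
               "baseline_end", "drawing_shown", "first_sketch_element",
               "task_end"),
    condition = c("isometric", "isometric", "isometric", "isometric",
                  "isometric", "orthographic", "orthographic", "orthographic",
                  "orthographic", "orthographic"),
    task_index = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2),
    stringsAsFactors = FALSE
  )
}
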