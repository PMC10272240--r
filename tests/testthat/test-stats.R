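test_that("median and MAD descriptives follow their definitions", {
  d <- med_mad(c(1, 2, 3), scaled = FALSE)
  expect_equal(d$Med, 2)
  expect_equal(d$MAD, 1)
  expect_equal(med_mad(rep(7, 10))$MAD, 0)
  # even n: mean of middle two
  expect_equal(med_mad(c(1, 2, 3, 10))$Med, 2.5)
  # scaled MAD is a consistent estimator of the normal SD
  set.seed(51)
  x <- rnorm(1000)
  expect_lt(abs(med_mad(x, scaled = TRUE)$MAD - 1), 0.1)
  expect_error(med_mad(numeric(0)), class = "eegtrp_empty_input")
})

test_that("the Shapiro-Wilk gate flags heavy tails and is calibrated on normals", {
  set.seed(52)
  heavy <- c(rnorm(450), rnorm(50, sd = 8))
  expect_lt(normality_check(heavy)$p, 0.05)
  rejections <- vapply(1:200, function(i) {
    normality_check(rnorm(50))$p < 0.05
  }, TRUE)
  expect_gt(mean(rejections), 0.01)
  expect_lt(mean(rejections), 0.10)
  expect_error(normality_check(rep(1, 10)), class = "eegtrp_degenerate_input")
  expect_error(normality_check(c(1, 2)), class = "eegtrp_bad_sample_size")
})

test_that("Bonferroni adjustment caps, scales and preserves order", {
  expect_equal(bonferroni_adjust(0.01, m = 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, m = 4), 1)
  expect_equal(bonferroni_adjust(0.2, m = 1), 0.2)
  p <- c(0.001, 0.04, 0.2, 0.01)
  expect_equal(order(bonferroni_adjust(p, m = 7)), order(p))
  expect_error(bonferroni_adjust(1.2), class = "eegtrp_bad_pvalue")
  expect_error(bonferroni_adjust(c(0.1, 0.2), m = 1), class = "eegtrp_bad_family")
})

test_that("ART alignment reproduces the hand-worked 2x2 ledger", {
  d <- expand.grid(subject = paste0("s", 1:4), A = c("a1", "a2"),
                   B = c("b1", "b2"), stringsAsFactors = FALSE)
  d$y <- c(5, 3, 4, 6, 9, 7, 8, 10, 2, 4, 3, 1, 12, 14, 13, 11)
  m <- art_model("y", c("A", "B"), subject = "subject")
  tr <- art_transform(d, m)
  # frozen values from the manual cell-mean alignment worked out beforehand
  expect_equal(tr$aligned_A,
               c(-3, -5, -4, -2, 4, 2, 3, 5, -4, -2, -3, -5, 3, 5, 4, 2))
  expect_equal(tr$aligned_B,
               c(0, -2, -1, 1, 0, -2, -1, 1, 0, 2, 1, -1, 0, 2, 1, -1))
  expect_equal(tr$aligned_A.B,
               c(2, 0, 1, 3, -1, -3, -2, 0, -2, 0, -1, -3, 1, 3, 2, 0))
  expect_equal(tr$rank_A,
               c(5.5, 1.5, 3.5, 7.5, 13.5, 9.5, 11.5, 15.5,
                 3.5, 7.5, 5.5, 1.5, 11.5, 15.5, 13.5, 9.5))
})

test_that("alignment strips every effect other than the aligned-for one", {
  set.seed(53)
  d <- expand.grid(subject = paste0("s", 1:6), A = c("a1", "a2"),
                   B = paste0("b", 1:3), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + ifelse(d$A == "a2", 1, 0) +
    as.numeric(factor(d$B)) * 0.5
  m <- art_model("y", c("A", "B"), subject = "subject")
  tr <- art_transform(d, m)
  # aligned-for-A column: marginal means of B and of A:B cells are zero
  for (b in unique(d$B)) {
    expect_lt(abs(mean(tr$aligned_A[d$B == b])), 1e-10)
  }
  # aligned-for-interaction: both main-effect margins vanish
  for (a in unique(d$A)) expect_lt(abs(mean(tr$aligned_A.B[d$A == a])), 1e-10)
  for (b in unique(d$B)) expect_lt(abs(mean(tr$aligned_A.B[d$B == b])), 1e-10)
  # ranks are a permutation of 1..N when there are no ties
  expect_setequal(tr$rank_A, seq_len(nrow(d)))
  # unbalanced design is rejected
  expect_error(art_transform(d[-1, ], m), class = "eegtrp_unbalanced_design")
})

test_that("ART F equals the by-hand repeated-measures F on pre-ranked data", {
  # single factor, data already ranks, no ties: alignment is a shift, so the
  # ART F must equal the parametric RM-ANOVA F computed from sums of squares
  set.seed(54)
  d <- expand.grid(subject = paste0("s", 1:10), A = paste0("a", 1:4),
                   stringsAsFactors = FALSE)
  d$y <- rank(rnorm(nrow(d)) + as.numeric(factor(d$A)))
  m <- art_model("y", "A", subject = "subject")
  res <- art_anova(d, m)
  oracle <- rm_anova_by_hand(d$y, d$subject, d$A)
  expect_equal(res$F, oracle$F, tolerance = 1e-10)
  expect_equal(res$df_effect, oracle$df1)
  expect_equal(res$df_error, oracle$df2)
  expect_equal(res$p, oracle$p, tolerance = 1e-10)
  expect_equal(res$eta_p_sq,
               res$F * res$df_effect / (res$F * res$df_effect + res$df_error),
               tolerance = 1e-12)
})

test_that("ART results are invariant to shifting and positive scaling", {
  set.seed(55)
  d <- expand.grid(subject = paste0("s", 1:8), A = c("a1", "a2"),
                   B = c("b1", "b2"), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + ifelse(d$A == "a2", 0.8, 0)
  m <- art_model("y", c("A", "B"), subject = "subject")
  r0 <- art_anova(d, m)
  d2 <- d; d2$y <- 3.7 * d$y + 11
  r1 <- art_anova(d2, m)
  expect_equal(r0$F, r1$F, tolerance = 1e-10)
  expect_equal(r0$p, r1$p, tolerance = 1e-10)
})

test_that("signed-rank V and exact p match exhaustive enumeration for n <= 8", {
  # every sign pattern over distinct magnitudes 1..n
  worst <- 0
  for (n in 1:8) {
    for (bits in 0:(2^n - 1)) {
      signs <- ifelse(bitwAnd(bits, 2^(0:(n - 1))) > 0, 1, -1)
      d <- signs * seq_len(n)
      w <- wilcoxon_signed_rank(d, rep(0, n))
      o <- brute_force_signed_rank(d)
      expect_identical(w$V, o$V)
      worst <- max(worst, abs(w$p - o$p))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("signed-rank handles zeros, ties, symmetry and known patterns", {
  # V for the documented pattern: ranks 1-4 positive, rank 5 negative
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3, 4, -5), rep(0, 5))$V, 10)
  # identical samples: degenerate result
  w0 <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(w0$degenerate)
  expect_equal(w0$V, 0)
  expect_equal(w0$p, 1)
  expect_equal(w0$r, 0)
  # symmetry without ties/zeros: V(x,y) + V(y,x) = n(n+1)/2
  set.seed(56)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(x, y)$V + wilcoxon_signed_rank(y, x)$V,
               12 * 13 / 2)
  # ties: agrees with the reference implementation's normal approximation
  xt <- c(1, 2, 2, 3, 5, 7, 7, 9)
  yt <- rep(0, 8)
  w <- wilcoxon_signed_rank(xt, yt)
  ref <- suppressWarnings(stats::wilcox.test(xt, yt, paired = TRUE,
                                             correct = TRUE))
  expect_equal(w$V, unname(ref$statistic))
  expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  expect_error(wilcoxon_signed_rank(1:3, 1:4), class = "eegtrp_length_mismatch")
  # literal effect-size variant
  wl <- wilcoxon_signed_rank(c(3, 1, 4, 1, 5), rep(0, 5), r_method = "statistic")
  expect_equal(wl$r, wl$V / sqrt(wl$n_effective))
})

test_that("posthoc decomposition finds a planted interaction and stays silent under the null", {
  # planted hemisphere x projection interaction in one band's TRP table
  m <- default_montage()
  set.seed(57)
  grid <- expand.grid(subject = sprintf("S%02d", 1:18),
                      projection = c("isometric", "orthographic"),
                      electrode = m$electrodes, stringsAsFactors = FALSE)
  grid$hemisphere <- unname(m$hemisphere_of[grid$electrode])
  grid$area <- unname(m$area_of[grid$electrode])
  grid$segment <- "seg1"; grid$band <- "theta"
  grid$trp <- rnorm(nrow(grid), 0, 0.1) +
    ifelse(grid$hemisphere == "LH" & grid$projection == "isometric", 0.4, 0)
  art <- art_anova(grid, art_model("trp", c("projection", "hemisphere")))
  expect_lt(art$p[art$effect == "projection:hemisphere"], 0.05)
  ph <- posthoc_decomposition(grid, art, m)
  hw <- ph[ph$family == "hemisphere_within_projection" & ph$scope == "isometric", ]
  expect_lt(hw$p_adj, 0.05)
  # the homologous-pair family has exactly 7 comparisons per projection
  pr_fam <- ph[ph$family_id == "pairs_within_projection.isometric", ]
  expect_equal(nrow(pr_fam), 7)
  expect_equal(pr_fam$p_adj, pmin(1, 7 * pr_fam$p))

  # null table with no significant effects: empty decomposition
  null_grid <- grid
  null_grid$trp <- rnorm(nrow(grid), 0, 0.1)
  art0 <- data.frame(effect = c("projection", "hemisphere"), p = c(0.4, 0.6))
  ph0 <- posthoc_decomposition(null_grid, art0, m)
  expect_equal(nrow(ph0), 0)
})
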