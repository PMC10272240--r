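#' Robust descriptives: median and MAD
#'
#' Median (mean of the middle two for even n) and median absolute deviation
#' around it. `scaled = TRUE` multiplies the MAD by 1.4826 (the consistency
#' constant for the normal distribution), matching common statistical
#' software defaults; `scaled = FALSE` gives the raw MAD.
#'
#' @param values numeric vector (length >= 1).
#' @param scaled apply the 1.4826 consistency constant (default TRUE).
#' @return List with `Med`, `MAD`, `n`.
#' @export
med_mad <- function(values, scaled = TRUE) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("empty input", "eegtrp_empty_input")
  med <- stats::median(values)
  mad <- stats::mad(values, center = med, constant = if (scaled) 1.4826 else 1)
  list(Med = med, MAD = mad, n = length(values))
}

#' Shapiro-Wilk normality check
#'
#' Annotates distributions in reports; the inferential pipeline is
#' nonparametric regardless of the outcome.
#'
#' @param values numeric vector, 3 <= n <= 5000, non-degenerate.
#' @return List with `W` and `p`.
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000", "eegtrp_bad_sample_size")
  }
  if (stats::sd(values) == 0) {
    abort("degenerate (constant) input", "eegtrp_degenerate_input")
  }
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, order-preserving. `m` defaults to the number of
#' p-values but may be larger (a family size exceeding the tested subset).
#'
#' @param pvals raw p-values in `[0, 1]`.
#' @param m family size (`m >= length(pvals)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", "eegtrp_bad_pvalue")
  }
  if (m < length(pvals)) {
    abort("family size m must be >= number of p-values", "eegtrp_bad_family")
  }
  stats::p.adjust(pvals, method = "bonferroni", n = m)
}
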