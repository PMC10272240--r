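#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (`n_effective` counts the non-zero pairs),
#' absolute differences receive midranks, and `V` is the sum of ranks of
#' positive differences. The two-sided p-value is exact (signed-rank null
#' distribution) when `n_effective <= exact_max_n` and there are no ties in
#' `|d|`; otherwise the normal approximation with tie and continuity
#' correction is used. The effect size is `r = |Z| / sqrt(n_effective)`
#' with Z from the (tie-corrected, continuity-corrected) normal
#' approximation; `r_method = "statistic"` instead reports the literal
#' `V / sqrt(n_effective)` (not scale-free; provided for comparability).
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max_n largest `n_effective` for which the exact distribution
#'   is used in the absence of ties (default 25).
#' @param r_method `"z"` (default) or `"statistic"`.
#' @return Object of class `wilcoxon_result`: list with `V`, `Z`, `p`,
#'   `p_adjusted` (NA until a family adjustment is applied), `r`,
#'   `n_effective`, `exact`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max_n = 25,
                                 r_method = c("z", "statistic")) {
  r_method <- match.arg(r_method)
  if (length(x) != length(y)) {
    abort("paired samples must have equal length", "eegtrp_length_mismatch")
  }
  d <- x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(V = 0, Z = 0, p = 1, p_adjusted = NA_real_, r = 0,
                          n_effective = 0L, exact = TRUE, degenerate = TRUE),
                     class = "wilcoxon_result"))
  }
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  ties <- anyDuplicated(abs(d)) > 0

  mu <- n * (n + 1) / 4
  tie_tab <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  sigma <- sqrt(sigma2)
  cc <- if (V == mu) 0 else 0.5 * sign(V - mu)
  Z <- if (sigma > 0) (V - mu - cc) / sigma else 0

  exact <- !ties && n <= exact_max_n
  if (exact) {
    p <- min(1, 2 * min(stats::psignrank(V, n),
                        1 - stats::psignrank(V - 1, n)))
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(Z)))
  }
  r <- if (r_method == "z") abs(Z) / sqrt(n) else V / sqrt(n)
  structure(list(V = V, Z = Z, p = p, p_adjusted = NA_real_, r = r,
                 n_effective = as.integer(n), exact = exact, degenerate = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("<wilcoxon_result> V = %g, Z = %.3f, p = %.3g%s, r = %.3f (n = %d%s)\n",
              x$V, x$Z, x$p,
              if (!is.na(x$p_adjusted)) sprintf(" (adj %.3g)", x$p_adjusted) else "",
              x$r, x$n_effective, if (x$exact) ", exact" else ""))
  invisible(x)
}
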