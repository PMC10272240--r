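#' Specify an aligned-rank-transform factorial model
#'
#' Describes the repeated-measures factorial: the response column, the
#' within-subject factors (all crossed), and the subject column. Tested
#' effects are all main effects and all two-way interactions.
#'
#' @param response response column name (e.g. `"trp"`).
#' @param factors character vector of within-subject factor column names.
#' @param subject subject column name (default `"subject"`).
#' @return Object of class `art_model`.
#' @export
art_model <- function(response = "trp", factors, subject = "subject") {
  if (length(factors) < 1) abort("at least one factor required", "eegtrp_bad_model")
  effects <- as.list(factors)
  if (length(factors) >= 2) {
    cmb <- utils::combn(factors, 2, simplify = FALSE)
    effects <- c(effects, cmb)
  }
  structure(list(response = response, factors = factors, subject = subject,
                 effects = effects,
                 effect_names = vapply(effects, paste, "", collapse = ":")),
            class = "art_model")
}

# Validate design: every subject x cell combination present, and the
# replication count constant across subjects within each cell.
check_design <- function(table, model) {
  for (v in c(model$factors, model$subject)) {
    if (!v %in% names(table)) {
      abort(sprintf("column '%s' missing from the table", v), "eegtrp_bad_model")
    }
  }
  cell <- interaction(table[model$factors], drop = FALSE, lex.order = TRUE)
  counts <- table(table[[model$subject]], cell)
  if (any(counts == 0)) {
    abort("incomplete design: some subject x cell combinations are empty",
          "eegtrp_unbalanced_design")
  }
  per_cell <- apply(counts, 2, function(col) length(unique(col)))
  if (any(per_cell != 1)) {
    abort("unbalanced design: replication differs across subjects within a cell",
          "eegtrp_unbalanced_design")
  }
  invisible(cell)
}

#' Aligned and ranked response columns, one per effect
#'
#' For every tested effect the response is aligned by removing the full
#' factorial cell mean and adding back that effect's estimate (computed
#' from unweighted cell means, so higher-order structure cancels), then
#' midrank-transformed over all observations. ANOVA on the ranks of the
#' column aligned for effect E is sensitive to E only.
#'
#' @param table long-format data frame.
#' @param model an [art_model()].
#' @return The input table with one extra pair of columns per effect:
#'   `aligned_<effect>` and `rank_<effect>` (`:` in effect names becomes `.`).
#' @export
art_transform <- function(table, model) {
  check_design(table, model)
  y <- table[[model$response]]
  facs <- lapply(model$factors, function(f) factor(table[[f]]))
  names(facs) <- model$factors

  # unweighted cell-mean array over the full factorial
  M <- tapply(y, facs, mean)
  grand <- mean(M)
  cell_idx <- do.call(cbind, lapply(facs, as.integer))
  cell_mean_obs <- M[cell_idx]
  resid <- y - cell_mean_obs

  marg <- function(dims) {
    if (length(dims) == length(model$factors)) return(M)
    apply(M, match(dims, model$factors), mean)
  }

  out <- table
  for (k in seq_along(model$effects)) {
    eff <- model$effects[[k]]
    if (length(eff) == 1) {
      est_tab <- marg(eff) - grand
      est <- est_tab[cell_idx[, match(eff, model$factors)]]
    } else {
      mAB <- marg(eff)
      mA <- marg(eff[1]) - grand
      mB <- marg(eff[2]) - grand
      est_tab <- mAB - outer(mA, rep(1, length(mB))) -
        outer(rep(1, length(mA)), mB) - grand
      est <- est_tab[cell_idx[, match(eff, model$factors), drop = FALSE]]
    }
    aligned <- resid + est
    nm <- gsub(":", ".", model$effect_names[k])
    out[[paste0("aligned_", nm)]] <- aligned
    out[[paste0("rank_", nm)]] <- rank(aligned)
  }
  out
}

#' Nonparametric factorial repeated-measures ANOVA via ART
#'
#' For each effect, a univariate repeated-measures ANOVA is run on that
#' effect's aligned ranks with the subject as the random blocking unit;
#' the effect is tested against its subject-by-effect interaction error
#' stratum. Only the aligned-for effect is reported from each fit. The
#' effect size is partial eta squared,
#' `F * df_effect / (F * df_effect + df_error)`.
#'
#' @param table long-format data frame.
#' @param model an [art_model()].
#' @return Data frame with one row per effect: `effect`, `F`, `df_effect`,
#'   `df_error`, `p`, `eta_p_sq`.
#' @export
art_anova <- function(table, model) {
  tab <- art_transform(table, model)
  for (f in model$factors) tab[[f]] <- factor(tab[[f]])
  tab[[model$subject]] <- factor(tab[[model$subject]])

  fixed <- paste(model$factors, collapse = " * ")
  err <- sprintf("Error(%s/(%s))", model$subject, fixed)

  rows <- list()
  for (k in seq_along(model$effects)) {
    eff_name <- model$effect_names[k]
    nm <- gsub(":", ".", eff_name)
    fml <- stats::as.formula(paste0("rank_", nm, " ~ ", fixed, " + ", err))
    fit <- stats::aov(fml, data = tab)
    sm <- summary(fit)
    stratum <- paste0("Error: ", model$subject, ":", eff_name)
    if (!stratum %in% names(sm)) {
      abort(sprintf("error stratum '%s' not found", stratum), "eegtrp_singular_stratum")
    }
    st <- sm[[stratum]][[1]]
    terms <- trimws(rownames(st))
    i <- match(eff_name, terms)
    ir <- match("Residuals", terms)
    if (is.na(i) || is.na(ir) || st[ir, "Df"] <= 0 ||
        !is.finite(st[i, "F value"])) {
      abort(sprintf("singular error stratum for effect '%s'", eff_name),
            "eegtrp_singular_stratum")
    }
    Fv <- st[i, "F value"]
    df1 <- st[i, "Df"]
    df2 <- st[ir, "Df"]
    rows[[k]] <- data.frame(
      effect = eff_name, F = Fv, df_effect = df1, df_error = df2,
      p = st[i, "Pr(>F)"],
      eta_p_sq = Fv * df1 / (Fv * df1 + df2),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
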