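# Post-hoc decomposition of significant ART effects into the study's
# pairwise Wilcoxon comparison families.

# Paired pull: values of `value_col` for rows matching `sel1`/`sel2`,
# aligned on `pair_keys`. Returns list(x, y) or NULL if empty.
paired_values <- function(df, sel1, sel2, pair_keys, value_col = "trp") {
  d1 <- df[sel1, , drop = FALSE]
  d2 <- df[sel2, , drop = FALSE]
  k1 <- do.call(paste, c(d1[pair_keys], sep = "\r"))
  k2 <- do.call(paste, c(d2[pair_keys], sep = "\r"))
  common <- intersect(k1, k2)
  if (length(common) == 0) return(NULL)
  list(x = d1[[value_col]][match(common, k1)],
       y = d2[[value_col]][match(common, k2)])
}

posthoc_row <- function(family, family_id, scope, group1, group2, xy,
                        mad_scaled, r_method) {
  w <- wilcoxon_signed_rank(xy$x, xy$y, r_method = r_method)
  d1 <- med_mad(xy$x, scaled = mad_scaled)
  d2 <- med_mad(xy$y, scaled = mad_scaled)
  data.frame(family = family, family_id = family_id, scope = scope,
             group1 = group1, group2 = group2,
             med1 = d1$Med, mad1 = d1$MAD, med2 = d2$Med, mad2 = d2$MAD,
             n_effective = w$n_effective, V = w$V, Z = w$Z, p = w$p,
             p_adj = NA_real_, r = w$r, stringsAsFactors = FALSE)
}

#' Decompose significant ART effects into pairwise Wilcoxon families
#'
#' Runs, for each significant main effect or two-way interaction from
#' [art_anova()], the matching family of pairwise Wilcoxon signed-rank
#' comparisons on one setting's TRP table (one segment and band):
#'
#' * `projection` main effect: orthographic vs isometric over the cortex,
#'   paired by subject and electrode.
#' * `hemisphere` main effect: LH vs RH, paired by subject, projection and
#'   homologous electrode pair.
#' * `area` main effect: FA vs RA per-subject area means, paired by subject
#'   and projection.
#' * `projection:hemisphere`: projection within each hemisphere, hemisphere
#'   within each projection, and the 7 homologous electrode pairs within
#'   each projection (family of 7).
#' * `projection:area`: projection within each area and FA vs RA (subject
#'   means) within each projection.
#' * `projection:electrode`: projection within each electrode (family of 14).
#'
#' Each family is Bonferroni-adjusted by its own comparison count.
#' Med/MAD are reported per compared cell.
#'
#' @param trp_table one setting's rows of the TRP table (single segment and
#'   band), with subject/projection/electrode/hemisphere/area columns.
#' @param art_results data frame(s) from [art_anova()] for this setting
#'   (rows from several models may be row-bound; duplicate effects are
#'   collapsed keeping the smallest p).
#' @param montage an `eeg_montage`.
#' @param alpha significance gate for decomposition (default 0.05).
#' @param mad_scaled scale MAD by 1.4826 (default TRUE).
#' @param r_method effect-size convention, see [wilcoxon_signed_rank()].
#' @param run_all run every family regardless of significance (default FALSE).
#' @return Data frame of comparisons (possibly zero rows when nothing is
#'   significant): family, family_id, scope, group1, group2, med1, mad1,
#'   med2, mad2, n_effective, V, Z, p, p_adj, r.
#' @export
posthoc_decomposition <- function(trp_table, art_results,
                                  montage = default_montage(), alpha = 0.05,
                                  mad_scaled = TRUE, r_method = "z",
                                  run_all = FALSE) {
  sig <- character()
  if (!is.null(art_results) && nrow(art_results) > 0) {
    sig <- unique(art_results$effect[art_results$p < alpha])
  }
  want <- function(effect) run_all || effect %in% sig

  df <- trp_table
  rows <- list()
  add <- function(r) if (!is.null(r)) rows[[length(rows) + 1L]] <<- r

  pair_labels <- vapply(montage$homologous_pairs, paste, "", collapse = "|")
  df$pair <- NA_character_
  for (i in seq_along(montage$homologous_pairs)) {
    df$pair[df$electrode %in% montage$homologous_pairs[[i]]] <- pair_labels[i]
  }

  if (want("projection")) {
    xy <- paired_values(df, df$projection == "orthographic",
                        df$projection == "isometric", c("subject", "electrode"))
    add(posthoc_row("projection", "projection", "cortex",
                    "orthographic", "isometric", xy, mad_scaled, r_method))
  }

  if (want("hemisphere")) {
    xy <- paired_values(df, df$hemisphere == "LH", df$hemisphere == "RH",
                        c("subject", "projection", "pair"))
    add(posthoc_row("hemisphere", "hemisphere", "cortex", "LH", "RH",
                    xy, mad_scaled, r_method))
  }

  area_means <- function(d) {
    ag <- stats::aggregate(trp ~ subject + projection + area, data = d, FUN = mean)
    ag
  }

  if (want("area")) {
    am <- area_means(df)
    xy <- paired_values(am, am$area == "FA", am$area == "RA",
                        c("subject", "projection"))
    add(posthoc_row("area", "area", "cortex", "FA", "RA", xy, mad_scaled, r_method))
  }

  if (want("projection:hemisphere")) {
    for (h in c("LH", "RH")) {
      xy <- paired_values(df, df$projection == "orthographic" & df$hemisphere == h,
                          df$projection == "isometric" & df$hemisphere == h,
                          c("subject", "electrode"))
      add(posthoc_row("projection_within_hemisphere", "projection_within_hemisphere",
                      h, "orthographic", "isometric", xy, mad_scaled, r_method))
    }
    for (pr in c("isometric", "orthographic")) {
      xy <- paired_values(df, df$projection == pr & df$hemisphere == "LH",
                          df$projection == pr & df$hemisphere == "RH",
                          c("subject", "pair"))
      add(posthoc_row("hemisphere_within_projection", "hemisphere_within_projection",
                      pr, "LH", "RH", xy, mad_scaled, r_method))
      for (i in seq_along(montage$homologous_pairs)) {
        pp <- montage$homologous_pairs[[i]]
        xy <- paired_values(df, df$projection == pr & df$electrode == pp[1],
                            df$projection == pr & df$electrode == pp[2],
                            "subject")
        add(posthoc_row("pairs_within_projection",
                        paste0("pairs_within_projection.", pr),
                        paste(pr, pair_labels[i]), pp[1], pp[2],
                        xy, mad_scaled, r_method))
      }
    }
  }

  if (want("projection:area")) {
    for (a in c("FA", "RA")) {
      xy <- paired_values(df, df$projection == "orthographic" & df$area == a,
                          df$projection == "isometric" & df$area == a,
                          c("subject", "electrode"))
      add(posthoc_row("projection_within_area", "projection_within_area", a,
                      "orthographic", "isometric", xy, mad_scaled, r_method))
    }
    am <- area_means(df)
    for (pr in c("isometric", "orthographic")) {
      xy <- paired_values(am, am$projection == pr & am$area == "FA",
                          am$projection == pr & am$area == "RA", "subject")
      add(posthoc_row("area_within_projection", "area_within_projection", pr,
                      "FA", "RA", xy, mad_scaled, r_method))
    }
  }

  if (want("projection:electrode")) {
    for (el in montage$electrodes) {
      xy <- paired_values(df, df$projection == "orthographic" & df$electrode == el,
                          df$projection == "isometric" & df$electrode == el,
                          "subject")
      add(posthoc_row("projection_within_electrode", "projection_within_electrode",
                      el, "orthographic", "isometric", xy, mad_scaled, r_method))
    }
  }

  if (length(rows) == 0) {
    return(data.frame(family = character(), family_id = character(),
                      scope = character(), group1 = character(),
                      group2 = character(), med1 = numeric(), mad1 = numeric(),
                      med2 = numeric(), mad2 = numeric(),
                      n_effective = integer(), V = numeric(), Z = numeric(),
                      p = numeric(), p_adj = numeric(), r = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  for (fid in unique(out$family_id)) {
    idx <- out$family_id == fid
    out$p_adj[idx] <- bonferroni_adjust(out$p[idx])
  }
  rownames(out) <- NULL
  out
}
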