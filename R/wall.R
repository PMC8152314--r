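#' Wall thickness as a function of outer diameter
#'
#' Per diameter class mean and SEM of ring wall thickness, plus the overall
#' Pearson correlation of wall thickness with outer diameter across rings.
#' In resistance-artery networks the wall thickens roughly linearly with
#' calibre, so the correlation is strongly positive; remodelling shifts
#' the per-class means.
#'
#' @param rings Ring table from [decompose()] (needs `outer_d_um`,
#'   `wall_um`).
#' @param binning A [diameter_binning()].
#' @param group Optional group label stored in the output.
#' @return List of class `wall_profile` with `table` (`data.frame`:
#'   `group`, `class_center_um`, `n`, `mean_wall_um`, `sem_um`; SEM is `NA`
#'   for classes with fewer than 2 rings), `pearson_r`, `p_value`.
#' @export
wall_profile <- function(rings, binning = diameter_binning(),
                         group = NA_character_) {
  stopifnot(nrow(rings) > 0)
  k <- classify_diameter(rings$outer_d_um, binning)
  keep <- !is.na(k)
  w <- rings$wall_um[keep]
  kk <- factor(k[keep], levels = seq_along(binning$centers))
  n <- as.integer(table(kk))
  mean_w <- tapply(w, kk, mean)
  sd_w <- tapply(w, kk, stats::sd)
  sem <- ifelse(n >= 2, sd_w / sqrt(n), NA_real_)
  ct <- stats::cor.test(rings$outer_d_um[keep], w, method = "pearson")
  structure(list(
    table = data.frame(group = group,
                       class_center_um = binning$centers,
                       n = n,
                       mean_wall_um = as.numeric(mean_w),
                       sem_um = as.numeric(sem)),
    pearson_r = unname(ct$estimate), p_value = ct$p.value,
    binning = binning, group = group),
    class = "wall_profile")
}

#' Compare wall-thickness profiles between groups
#'
#' Two-way ANOVA of ring wall thickness on group and diameter class with
#' their interaction, followed by per-class Tukey HSD pairwise group
#' comparisons. Sums of squares are type II, appropriate for the unbalanced
#' layouts that pooled ring tables produce. Diameter classes not occupied
#' in every group are excluded with a message. The unit of analysis is the
#' ring; with thousands of rings per network the test is extremely
#' powerful, and rings from one animal are not independent -- treat the
#' p-values accordingly.
#'
#' @param rings_by_group `data.frame` with columns `group`, `outer_d_um`,
#'   `wall_um`: pooled rings of two or more groups.
#' @param binning A [diameter_binning()].
#' @return List of class `wall_anova` with `anova` (`data.frame`: `effect`,
#'   `F`, `df`, `df_resid`, `p`), `tukey` (`data.frame`: `class_center_um`,
#'   `comparison`, `diff_um`, `p_adj`), `excluded_classes`.
#' @export
compare_wall_profiles <- function(rings_by_group, binning = diameter_binning()) {
  stopifnot(all(c("group", "outer_d_um", "wall_um") %in% names(rings_by_group)))
  groups <- unique(rings_by_group$group)
  stopifnot(length(groups) >= 2)
  k <- classify_diameter(rings_by_group$outer_d_um, binning)
  d <- data.frame(group = factor(rings_by_group$group),
                  class = k, wall = rings_by_group$wall_um)[!is.na(k), ]

  occ <- table(d$group, d$class)
  full <- as.integer(colnames(occ)[apply(occ > 0, 2, all)])
  present <- sort(unique(d$class))
  excluded <- binning$centers[setdiff(present, full)]
  if (length(excluded) > 0)
    message("classes not occupied in every group excluded: ",
            paste(sort(excluded), collapse = ", "), " um")
  d <- d[d$class %in% full, ]
  d$class <- factor(binning$centers[d$class])

  fit <- stats::lm(wall ~ group * class, data = d)
  a2 <- car::Anova(fit, type = 2)
  eff <- rownames(a2)
  keep <- eff != "Residuals"
  anova_tab <- data.frame(
    effect = eff[keep],
    F = a2[keep, "F value"],
    df = a2[keep, "Df"],
    df_resid = a2["Residuals", "Df"],
    p = a2[keep, "Pr(>F)"])

  tukey <- do.call(rbind, lapply(levels(d$class), function(cl) {
    dd <- d[d$class == cl, ]
    if (length(unique(dd$group)) < 2 || nrow(dd) < 3) return(NULL)
    tk <- stats::TukeyHSD(stats::aov(wall ~ group, data = dd))$group
    data.frame(class_center_um = as.numeric(cl),
               comparison = rownames(tk),
               diff_um = tk[, "diff"],
               p_adj = tk[, "p adj"])
  }))
  rownames(tukey) <- NULL
  structure(list(anova = anova_tab, tukey = tukey,
                 excluded_classes = sort(excluded)),
            class = "wall_anova")
}
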