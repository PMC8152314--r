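#!/usr/bin/env Rscript
# Step 5: wall thickness as a function of outer diameter, with two-way
# ANOVA (training x diameter class) and per-class Tukey contrasts for the
# sedentary-versus-exercised comparison within each sex.

library(coronet)

rings <- read.csv(file.path("results", "rings_pooled.csv"))

profiles <- do.call(rbind, lapply(unique(rings$group), function(g)
  wall_profile(rings[rings$group == g, ], group = g)$table))
write.csv(profiles, file.path("results", "wall_profiles.csv"),
          row.names = FALSE)

report <- list()
for (sex in c("M", "F")) {
  pair <- paste0(sex, c("Sed", "Ex"))
  d <- rings[rings$group %in% pair, c("group", "outer_d_um", "wall_um")]
  res <- suppressMessages(compare_wall_profiles(d))
  cat("\n", pair[1], "vs", pair[2], "two-way ANOVA:\n")
  print(res$anova, row.names = FALSE)
  sig <- res$tukey[res$tukey$p_adj < 0.05, ]
  cat("Diameter classes with a training difference (Tukey p < 0.05):",
      if (nrow(sig) > 0) paste(sig$class_center_um, collapse = ", ")
      else "none", "um\n")
  report[[paste(pair, collapse = "_vs_")]] <-
    list(anova = res$anova, tukey_significant_classes = sig$class_center_um)
}
jsonlite::write_json(report, file.path("results", "wall_anova.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
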