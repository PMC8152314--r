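#!/usr/bin/env Rscript
# Step 7: bundle the cohort's headline numbers from the previous steps
# into one machine-readable report.

res <- function(...) file.path("results", ...)
stopifnot(file.exists(res("murray_report.json")),
          file.exists(res("spectra_comparisons.json")),
          file.exists(res("wall_anova.json")))

report <- list(
  cohort = read.csv(res("cohort_summary.csv")),
  murray = jsonlite::read_json(res("murray_report.json")),
  spectra_chi2 = jsonlite::read_json(res("spectra_comparisons.json")),
  wall_anova = jsonlite::read_json(res("wall_anova.json")),
  echo_means = aggregate(
    cbind(lv_mass_index_g_kg, ef_pct, fs_pct) ~ group,
    read.csv(res("echo_derived.csv")), mean))

jsonlite::write_json(report, res("report.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote", res("report.json"), "\n")
for (g in setdiff(names(report$murray), "residual_anova_p"))
  cat(sprintf("%-5s gamma_hat %.3f\n", g, report$murray[[g]]$gamma_hat))
cat("spectra comparisons:", paste(names(report$spectra_chi2), collapse = ", "),
    "\n")
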