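#!/usr/bin/env Rscript
# Stage 4: human-readable summary of the whole run.
#
# Collates participant flow, group-mean diurnal curves, normalized
# best-fold confusion matrices and the metric table into
# results/report.txt.

library(actikoa)

prov <- yaml::read_yaml("results/scenarios/provenance.yaml")
lines <- c("Diurnal activity and early KOA risk - analysis report",
           strrep("=", 54), "",
           sprintf("simulated participants: %d", prov$n_simulated),
           sprintf("after eligibility filters: %d", prov$n_kept))
scenario_names <- c("Healthy vs KOA", "Prodromal vs Diagnosed",
                    "Healthy vs Prodromal (5y)")
for (s in 1:3) {
  dat <- utils::read.csv(sprintf("results/scenarios/scenario_%d.csv", s))
  summ <- yaml::read_yaml(sprintf("results/cv/summary_%d.yaml", s))
  conf <- utils::read.csv(sprintf("results/cv/confusion_best_%d.csv", s),
                          row.names = 1)
  lines <- c(lines, "", sprintf("Scenario %d: %s (%d vs %d)", s,
                                scenario_names[s], sum(dat$label == 0),
                                sum(dat$label == 1)),
             "  mean diurnal activity by class (hours 0..23):")
  for (lb in 0:1) {
    prof <- colMeans(as.matrix(dat[dat$label == lb,
                                   sprintf("h%02d", 0:23)]))
    lines <- c(lines, sprintf("    class %d: %s", lb,
                              paste(sprintf("%.1f", prof), collapse = " ")))
  }
  lines <- c(lines,
             "  best-fold normalized confusion (rows = true class):",
             sprintf("    true 0: %.3f %.3f", conf[1, 1], conf[1, 2]),
             sprintf("    true 1: %.3f %.3f", conf[2, 1], conf[2, 2]),
             sprintf("  accuracy %.1f +/- %.1f%%, F1 %.3f, sens %.3f, AUC %.3f",
                     100 * summ$mean$accuracy, 100 * summ$sd$accuracy,
                     summ$mean$f1_macro, summ$mean$sensitivity_macro,
                     summ$mean$auc_macro),
             sprintf("  chi-squared p = %.2g, proportion z p = %.2g, t-test p = %.2g",
                     summ$chi_squared$p_value,
                     summ$proportion_test$p_value, summ$t_test$p_value))
}
writeLines(paste(lines, collapse = "\n"), "results/report.txt")
cat(paste(lines, collapse = "\n"), "\n")
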