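#!/usr/bin/env Rscript
# Stage 4: repeated-measures statistics over the metric table.
#
# For every metric x region: one-way RM-ANOVA across frame counts with
# the Greenhouse-Geisser correction, Bonferroni-adjusted sequential post
# hoc t-tests, the optimal number of averaged frames (smallest n with no
# significant sequential gain beyond it), percent differences from the
# reference to the 5- and 10-frame averages, and the area-coverage
# conversion of the 10-frame length densities.

suppressMessages(library(rpcavg))

metrics <- read.csv("results/metrics.csv")
st <- stats_stage(metrics, n_values = 1:10, alpha = 0.05)

write.csv(st$percent_diff, "results/percent_differences.csv", row.names = FALSE)
write.csv(st$optimal, "results/optimal_frames.csv", row.names = FALSE)
anova_json <- lapply(st$anova, function(x)
  list(metric = x$metric, region = x$region, F = x$anova$F,
       df_num = x$anova$df_num, df_den = x$anova$df_den,
       epsilon_gg = x$anova$epsilon_gg, p_gg = x$anova$p_gg))
jsonlite::write_json(anova_json, "results/anova.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
plot_density_boxplot(metrics, "results/density_boxplot.png")

message("reference -> 10-frame percent differences (mean over regions):")
for (m in unique(st$percent_diff$metric)) {
  message(sprintf("  %-24s %+7.1f %%", m,
                  mean(st$percent_diff$pct_diff_10[st$percent_diff$metric == m],
                       na.rm = TRUE)))
}
message("optimal averaged frames by metric (median over regions):")
for (m in unique(st$optimal$metric)) {
  message(sprintf("  %-24s %d", m,
                  as.integer(median(st$optimal$optimal_frames[st$optimal$metric == m]))))
}
d10 <- metrics[metrics$n_frames == 10 & !metrics$excluded, ]
message(sprintf("10-frame mean density %.1f mm^-1, area coverage %.1f %%, mean ICD %.1f um",
                mean(d10$density_mm_inv),
                mean(area_coverage_from_length_density(d10$density_mm_inv)),
                mean(d10$icd_um, na.rm = TRUE)))
message("tables -> results/percent_differences.csv, results/optimal_frames.csv, results/anova.json")
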