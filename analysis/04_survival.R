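#!/usr/bin/env Rscript
# Step 4: desiccation-assay statistics.
#
# Recovery rates per replicate (recovered / total), condition means and
# SDs, and the condition comparison: Student's t-test for two conditions,
# Tukey-Kramer over the studentized-range distribution for three or more.

suppressPackageStartupMessages(library(tardiquant))

src <- "results/simulated_experiment"
out <- "results/survival"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

assays <- read_survival(file.path(src, "survival_counts.tsv"))
res <- survival_test(assays, test = "auto")

readr::write_tsv(res$summary, file.path(out, "recovery_summary.tsv"))
readr::write_tsv(res$comparisons, file.path(out, "comparisons.tsv"))

for (i in seq_len(nrow(res$summary))) {
  message(sprintf("%s: mean recovery %.1f%% (SD %.1f%%, n = %d)",
                  res$summary$condition[i], 100 * res$summary$mean_rate[i],
                  100 * res$summary$sd_rate[i], res$summary$n[i]))
}
for (i in seq_len(nrow(res$comparisons))) {
  message(sprintf("%s vs %s: %s p = %.4f",
                  res$comparisons$group1[i], res$comparisons$group2[i],
                  res$test, res$comparisons$p[i]))
}
message("wrote ", out)
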