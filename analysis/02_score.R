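#!/usr/bin/env Rscript
# Stage 2 — composite scoring and descriptive country comparison.
#
# Scores every composite (mental health mean, resilience / life-stress /
# conflict sums, work-stress item, job-change count, father involvement),
# writes a per-respondent score table, and the descriptives-with-tests
# country comparison (ANOVA for continuous, chi-square for categorical).

suppressPackageStartupMessages(library(maternalcv))
out <- "scratch/run"
tab_out <- "results/run"
dir.create(tab_out, showWarnings = FALSE, recursive = TRUE)

scored <- list()
for (cc in c("CN", "IT", "NL")) {
  cohort <- read_cohort(file.path(out, sprintf("cohort_%s.csv", cc)))
  scored[[cc]] <- score_cohort(cohort)
  write.csv(scored[[cc]][, c("respondent_id", names(scale_catalog()))],
            file.path(out, sprintf("scores_%s.csv", cc)), row.names = FALSE)
}

desc <- group_comparison_table(scored)
write.csv(desc, file.path(tab_out, "descriptives.csv"), row.names = FALSE)
cat("score summaries (mean mental health / resilience):\n")
for (cc in names(scored))
  cat(sprintf("  %s: mental_health %.2f, resilience %.1f, r(jobchange, workstress) %.3f\n",
              cc, mean(scored[[cc]]$mental_health),
              mean(scored[[cc]]$resilience),
              pearson_correlation(scored[[cc]]$job_change_index,
                                  scored[[cc]]$work_stress)$r))
cat("descriptives written to", file.path(tab_out, "descriptives.csv"), "\n")
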