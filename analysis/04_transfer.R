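#!/usr/bin/env Rscript
# Stage 4 — cross-country transfer validation.
#
# Each country's winning factor subset is refitted under repeated 10-fold CV
# on every country's data (coefficients re-estimated on target training
# folds; only the subset transfers). The per-repeat RMSE distributions of
# the 9 source-model x target-data pairs are summarized and exported in
# long format for box/density plotting.

suppressPackageStartupMessages(library(maternalcv))
out <- "scratch/run"
tab_out <- "results/run"
cv <- cv_config(k = 10, repeats = 200, seed = 29, engine = "gram")
catalog <- factor_catalog()

best <- jsonlite::read_json(file.path("results/run", "best_models.json"),
                            simplifyVector = TRUE)
cohorts <- lapply(list(CN = "CN", IT = "IT", NL = "NL"), function(cc)
  score_cohort(read_cohort(file.path(out, sprintf("cohort_%s.csv", cc)))))

tr <- cross_fit(best, cohorts, catalog, cv)
write.csv(as.data.frame(tr), file.path(out, "transfer_long.csv"),
          row.names = FALSE)
s <- summarize_transfer(tr)
write.csv(s$summary, file.path(tab_out, "transfer_summary.csv"),
          row.names = FALSE)

cat("median RMSEp by source model (rows) on target data (columns):\n")
med <- with(as.data.frame(tr), tapply(rmse, list(source, target), median))
print(round(med, 4))
own_best <- sapply(colnames(med), function(tgt)
  rownames(med)[which.min(med[, tgt])] == tgt)
cat("own model best on own data:", paste(names(own_best), own_best,
                                         collapse = ", "), "\n")
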