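#!/usr/bin/env Rscript
# Stage 5 — robust standardized refits and the moderation analysis.
#
# Refits each country's winning model by OLS on standardized outcome and
# continuous predictors with HC3 sandwich standard errors and Wald tests
# (regression-table analog), exports the all-catalog coefficient display
# with non-selected factors fixed to zero, and runs the resilience-by-stress
# moderation analysis with simple slopes at +/-1 s.d. of resilience.

suppressPackageStartupMessages(library(maternalcv))
out <- "scratch/run"
tab_out <- "results/run"
catalog <- factor_catalog()

best <- jsonlite::read_json(file.path("results/run", "best_models.json"),
                            simplifyVector = TRUE)
coefs <- list()
for (cc in c("CN", "IT", "NL")) {
  scored <- score_cohort(read_cohort(file.path(out,
                                               sprintf("cohort_%s.csv", cc))))
  fit <- fit_winning_model(scored, catalog, best[[cc]])
  tab <- as.data.frame(fit)
  tab$adj_r_squared <- attr(fit, "adj_r_squared")
  write.csv(tab, file.path(tab_out, sprintf("fit_%s.csv", cc)),
            row.names = FALSE)
  coefs[[cc]] <- coefficient_export(fit, catalog, cc)
  cat(sprintf("%s: adjusted R2 = %.3f; significant terms: %s\n", cc,
              attr(fit, "adj_r_squared"),
              paste(fit$term[fit$p < 0.05 & fit$term != "(Intercept)"],
                    collapse = ", ")))

  focal <- intersect(c("life_stress", "work_stress"), best[[cc]])
  if ("resilience" %in% best[[cc]] && length(focal)) {
    mod <- moderation_analysis(scored, catalog, best[[cc]], "resilience",
                               focal)
    write.csv(mod$simple_slopes,
              file.path(tab_out, sprintf("moderation_%s.csv", cc)),
              row.names = FALSE)
    for (i in seq_len(nrow(mod$interactions)))
      cat(sprintf("  moderation %s: beta = %.3f, p = %.3f\n",
                  mod$interactions$term[i], mod$interactions$estimate[i],
                  mod$interactions$p[i]))
  }
}
write.csv(do.call(rbind, c(coefs, list(make.row.names = FALSE))),
          file.path(tab_out, "coefficients_long.csv"), row.names = FALSE)
cat("fit tables written under", tab_out, "\n")
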