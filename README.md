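# maternalcv

Cross-validated all-subsets model selection for multi-country maternal
mental health surveys.

## The problem

During a pandemic lockdown, which factors best predict maternal mental
health — and are they the same across countries? Given cohorts of mothers
from China, Italy and the Netherlands with composite scores for mental
health symptoms, resilience, pandemic-related life and work stress, job
changes, family conflict, father involvement, grandparental child-care
support and eight demographic characteristics, the analysis:

1. enumerates **all 2^15 = 32,768 subsets** of the 15 candidate factors;
2. ranks them per country by **repeated 10-fold cross-validated RMSE of
   prediction** (RMSEp), tallying for each model the percentage of repeats
   in which it attains the lowest prediction error of all models;
3. **transfers** each country's winning model to the other countries' data
   (re-estimating coefficients, keeping the factor subset) to compare the
   resulting RMSE distributions;
4. refits each winning model with **standardized coefficients and HC3
   robust (sandwich) standard errors**, and tests whether resilience
   moderates the effect of pandemic stress via centered interaction terms
   and simple slopes.

For a model *m* and fold partition into k = 10 folds, each fold is
predicted from an OLS fit on the other nine, and

```
RMSEp(m) = sqrt( (1/n) * sum_i ( y_i - yhat_{i, -fold(i)} )^2 )
```

averaged over R = 200 random partitions shared by all models within a
repeat.

Because the underlying survey data are not public, the package includes a
seeded **synthetic cohort generator** that emulates the surveys'
statistical structure — Likert items calibrated to the instruments'
Cronbach's alphas (0.96 for the 27-item mental-health composite, 0.85
resilience, 0.82 life stress, 0.85 conflict, 0.89 father involvement),
four symptom subscales correlating inside the reported 0.776–0.961 band, a
job-change/work-stress correlation of ≈ 0.35, country-specific
grandparental-support prevalences (53.6% / 18.3% / 9.4%) and sample sizes
(922 / 641 / 900), and country-specific standardized effects on a latent
outcome. All downstream stages are developed and tested against this
generator; see `vignettes/methods.Rmd` for what it does and does not
emulate.

## Worked example

```r
library(maternalcv)

# a Dutch-style cohort at reduced size, scored
cfg    <- country_preset("NL", n = 400, seed = 1)
scored <- score_cohort(apply_inclusion_filter(generate_cohort(cfg)))

# exhaustive search over an 8-factor catalog, 25 repeats of 10-fold CV
cat8 <- factor_catalog()[c("resilience", "life_stress", "work_stress",
                           "family_conflict", "grandparental_support",
                           "education", "employment", "n_children")]
class(cat8) <- "factor_catalog"
res <- run_search(scored, cat8, cv_config(k = 10, repeats = 25, seed = 2))
top_models_table(res, 3)
#>   model                                                          formula
#> 1    80 mental_health ~ resilience + life_stress + work_stress + fami...
#> 2   208 mental_health ~ resilience + life_stress + work_stress + fami...
#> 3   112 mental_health ~ resilience + life_stress + work_stress + fami...
#>   n_factors wins win_pct mean_rmsep
#> 1         5   12      48  0.9378423
#> 2         6    9      36  0.9383663
#> 3         6    3      12  0.9396970
```

The top row says: the subset {resilience, life stress, work stress, family
conflict, employment} had the lowest prediction error in 48% of the 25
cross-validation repeats, with a mean held-out RMSE of 0.938 on the 1-5
mental-health score scale. The stress/resilience/conflict core appears in
every top model; the runner-up models differ only in which extra
demographic factor they add.

```r
fit <- fit_winning_model(scored, cat8, best_model(res))
fit[, c("term", "estimate", "robust_se", "p")]
#>                    term    estimate  robust_se            p
#> 1           (Intercept) -0.05796213 0.05210131 2.659281e-01
#> 2            resilience -0.17506469 0.04736880 2.192119e-04
#> 3           life_stress  0.18268179 0.04846986 1.639181e-04
#> 4           work_stress  0.15045895 0.04737217 1.492674e-03
#> 5       family_conflict  0.22666336 0.04540443 5.972714e-07
#> 6 employment:unemployed  0.30110196 0.12374210 1.496180e-02
```

Standardized betas with HC3 robust errors: resilience is protective
(-0.18), family conflict (+0.23) and both stress dimensions (+0.18, +0.15)
are risks, and unemployment raises symptom levels (+0.30 relative to
employed mothers), each significant at n = 400.

The full three-country analysis — simulate, score, search all 32,768
models, transfer-validate, refit — is scripted under `analysis/`
(`01_simulate.R` … `06_report.R`); each stage writes its tables under
`results/run/`.

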