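---
title: "Cross-validated model selection for multi-country maternal mental health surveys: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-validated model selection for multi-country maternal mental health surveys: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis this package implements

`maternalcv` implements, as a tested and reusable pipeline, a
cross-validated model-selection analysis of maternal mental health across
three country cohorts (China, Italy, the Netherlands), together with a
synthetic cohort generator that emulates the statistical structure such a
survey produces. The pipeline has five computational stages:

1. **Cohort generation** (`generate_cohort()`, `country_preset()`):
   respondent-level tables with demographics, Likert item responses for six
   multi-item instruments, a single work-stress item, and 13 binary
   job-change indicators.
2. **Scoring** (`score_cohort()`): composite scale scores, inclusion
   filtering, reliabilities and descriptives.
3. **Exhaustive search** (`run_search()`): all \(2^{15} = 32\,768\) subsets
   of 15 candidate risk/protective factors, ranked by repeated 10-fold
   cross-validated root mean square error of prediction (RMSEp) with
   winner-frequency tallies.
4. **Transfer validation** (`cross_fit()`): each country's winning factor
   subset refitted on every country's data; the 9 RMSE distributions
   summarize how well a model selected in one country travels.
5. **Robust refits and moderation** (`fit_winning_model()`,
   `moderation_analysis()`): standardized OLS coefficients of the winning
   models with HC3 sandwich standard errors and Wald tests, and
   resilience-by-stress interactions with simple slopes.

The numbered scripts under `analysis/` run these stages in order on the
three preset cohorts and write their tables under `results/run/`.

# The model search

## Candidate factors and design coding

The catalog (`factor_catalog()`) holds 15 factors: seven survey-derived
(resilience, pandemic life stress, pandemic work stress, job-change index,
family conflict, father involvement, grandparental child-care support) and
eight demographic (marital status, maternal age band, education,
employment, physical health, household income, number of children, age of
the youngest child). Categorical factors are reference-coded as dummy
blocks (reference levels: married, age 18–30, college-and-below education,
employed, poor physical health) and enter or leave a model as a whole
block; with the intercept the full design has 20 columns. Household income
enters as a single ordinal-continuous term since no bracket definitions are
available.

## Repeated k-fold cross-validation

For a model \(m\) and fold partition \(\pi\), each fold is predicted by an
OLS fit on the remaining \(k-1\) folds and

\[\mathrm{RMSEp}(m, \pi) = \sqrt{\tfrac{1}{n}\sum_{i=1}^{n}
  \left(y_i - \hat y_{i,-\pi(i)}\right)^2}.\]

Partitions are balanced (fold sizes differ by at most one) and derived
deterministically from the configuration seed; within one repeat a single
partition is shared by **all** models, so the per-repeat winner — the model
with minimal RMSEp — is a fair comparison. A model's *winner percentage*
over \(R\) repeats (default \(R = 200\)) measures the stability of its
selection; the package reports it alongside the mean RMSEp, ranking the
top-\(k\) table by winner percentage first and mean RMSEp second (the
winner-frequency interpretation is the one the tally is defined by; mean
RMSEp breaks ties).

The description of 10-fold cross-validation as training on *one* subset and
validating on the other nine inverts the standard orientation in which
training uses \(k-1\) folds. The standard orientation is the default here
(`orientation = "standard"`), matching the cited cross-validation
methodology; `orientation = "invert"` is available as a configuration
switch for the literal reading.

## Two engines, one contract

The sweep over 32,768 models × 10 folds × 200 repeats is 65.5 million small
least-squares fits. The default **gram** engine (C++): per repeat it
accumulates fold-wise cross-products \(X_f'X_f\), \(X_f'y_f\), \(y_f'y_f\);
a model's training normal equations for fold \(f\) are the totals minus
fold \(f\)'s contribution restricted to the model's columns, and the
held-out error comes from the same fold cross-products, so no per-row work
occurs inside the model loop. The **naive** engine refits each fold in R
via an SVD least-squares solve. The two paths must agree within
\(10^{-8}\) RMSEp (property-tested); the full 15-factor, \(n \approx 900\),
\(R = 200\) search runs in minutes on one CPU via the gram path.

Numerical choices:

* Rank-deficient training systems (e.g. a dummy level absent from a
  training split) use the Moore–Penrose minimum-norm solution in both
  engines instead of erroring, keeping the sweep uninterrupted; only an
  *empty* training set is an error.
* Winner determination treats RMSEp values within \(10^{-7}\) (relative) of
  the minimum as tied — differences below the engines' own agreement floor
  are numerical noise — and resolves ties by fewest included factors, then
  canonical (mask-ascending) order. Without this, a noise-free outcome
  would crown an arbitrary exact-fit superset by last-bit ordering.

## What the selection criterion can and cannot do

k-fold cross-validation with a fixed number of folds is not a consistent
model selector: the probability that some superset of the true model beats
it out-of-sample does not vanish as \(n\) grows, because a spurious sample
correlation of order \(1/\sqrt{n}\) buys an apparent error reduction of the
same order as the parsimony penalty \(\sigma^2/n\). The true model's winner
percentage therefore climbs with \(n\) while underfitting still dominates
and then plateaus below 100%. The selection-consistency test runs in that
climbing regime (three true factors of standardized effect 0.06 against
five irrelevant ones, noise s.d. 1, \(n \in \{200, 800, 3200\}\)), and
averages the winner percentage over 20 generated datasets per sample size
because the dominant variance is between datasets, not between repeats.

# Transfer validation

Only the factor *subset* transfers between countries: coefficients are
always re-estimated on the target cohort's training folds. (Transporting
frozen coefficients would additionally require comparable score scales
across cohorts; refitting is also the natural reading of "fitting each
country's best model to the dataset" of another country.) The same repeat
seeds are used for all 9 source × target pairs so that distribution
differences reflect model and data, not partitions. Summaries report
five-number statistics plus a distribution-overlap coefficient (integral of
the pointwise minimum of kernel density estimates, normalized so identical
samples give 1).

The diagonal-optimality property — each country's own model attains the
lowest median RMSEp on its own data — is a *qualitative* expectation that
needs detectable between-country differences to be observable at
\(n = 800\). `transfer_scenario_config()` documents the scenario used to
check it: the four shared factors keep their preset effects while each
country's unique factors carry standardized effects of magnitude
0.15–0.30. At the presets' weaker country-unique effects (\(|\beta| \sim
0.1\)) the own-model margin (~2% of error variance) is smaller than
dataset-level RMSE fluctuation at this sample size, so the property holds
only on average, not per seed.

# Inference on the winning models

"Robust standard OLS regression" is implemented as OLS point estimates with
heteroskedasticity-consistent **HC3** sandwich standard errors and Wald
\(z\) tests, with the model-level adjusted \(R^2\) taken from the plain OLS
fit — consistent with reporting Wald p-values next to an OLS-based adjusted
\(R^2\). M-estimation would be the alternative reading; HC3 was chosen and
the choice is localized in `robust_fit()`. Standardization scales the
outcome and continuous predictors to unit variance (n−1 denominator) and
leaves dummies at 0/1, so categorical coefficients remain level contrasts.
No multiple-testing correction is applied, matching per-term Wald
reporting. The coefficient export writes a zero for every factor not in the
winning model so that country displays are directly comparable.

Moderation augments the winning model with products of the standardized
moderator (resilience) and standardized focal stress terms; because both
are centered, the simple slope at mean moderator equals the focal main
effect, and slopes at ±1 s.d. follow by construction with delta-method
robust standard errors.

# The synthetic cohort generator

## What it emulates

The generator reproduces the *statistical structure* the analysis assumes,
so that every downstream stage is testable without any survey data:

* **Item-level Likert responses with stated reliabilities.** Each
  multi-item scale draws its items as
  \(z_{ij} = \sqrt{\rho_\ell}\, T_i + \sqrt{1-\rho_\ell}\,
  \varepsilon_{ij}\) from a standardized latent trait \(T\), discretized at
  fixed equiprobable thresholds. Compound symmetry is the simplest
  structure consistent with a reported alpha (item covariances are not
  reported). The target inter-item correlation follows from inverting
  standardized alpha, \(\rho = \alpha / (k - \alpha(k-1))\); because
  discretization attenuates correlations, the latent \(\rho_\ell\) is
  obtained by numerically inverting the exact ordinal-scale correlation
  (bivariate-normal quadrature), so the target is met on the *observed*
  scale. This matters most for the 4-level life-stress items, where naive
  latent calibration would miss the ±0.02 alpha tolerance.
* **Four correlated symptom subscales.** The 27 mental-health items load on
  somatization (6), depression (5), anxiety (6) and post-traumatic stress
  (10) subscale factors that share one general factor — mirroring the
  one-general-factor account of the symptom structure without implementing
  a factor analysis. With the default loading \(\lambda = \sqrt{0.95}\) and
  the within-subscale correlation solved so the 27-item composite attains
  alpha 0.96, the implied subscale score correlations fall at 0.80–0.86,
  inside the reported 0.776–0.961 band.
* **Outcome structure.** The latent outcome is
  \(y^* = \sum_f \beta_f x_f + \sum_{ab} \beta_{ab} x_a x_b +
  \varepsilon\) over *standardized* factor columns (continuous traits,
  dummies and counts are all z-scored within the sample), so the configured
  effects are standardized effects; the general symptom factor is the
  standardized \(y^*\). A binary factor with effect \(\beta\) therefore
  separates group means of \(y^*\) by \(\beta/\mathrm{sd}(x)\). The
  generated truth (latent outcome, traits, standardized design) rides along
  in `attr(cohort, "latent")` for recovery diagnostics.
* **Country-specific prevalences and effects.** Grandparental support
  53.6% / 18.3% / 9.4% and sample sizes 922 / 641 / 900 for CN / IT / NL.
  Effect *signs* follow the reported country profiles: pandemic stress and
  family conflict harmful and resilience protective everywhere;
  grandparental support, marriage and more children protective in China,
  with high education, high income and poor physical health as risks;
  younger age and poor physical health as risks in Italy; high education
  and unemployment as risks in the Netherlands. Magnitudes (0.08–0.25
  standardized) are free parameters chosen once at values typical for
  survey risk factors; with noise s.d. 1 the generating equation explains
  roughly 20% of the latent outcome's variance (less on the scored
  composite after measurement attenuation), in the range such surveys
  report.
* **Job changes and work stress.** The 13 binary job-change indicators
  (base rate 0.25, loading 0.7) share a latent propensity correlated with
  the work-stress trait; the propensity correlation default (0.42) was
  calibrated once at \(n = 50{,}000\) so the observed correlation between
  the job-change *index* and the 1–10 work-stress *item* is ≈ 0.35, the
  value the instrument validation reports.

Every random block draws from its own named substream of the global seed
(`substream_seed()`), so adding or removing a scale does not perturb the
draws of the others, and identical configurations are byte-identical.

## What it does not emulate

Demographics are sampled independently per respondent (only marginals are
available — no copula between, say, age and income); scale means and
standard deviations per country are not reported and default to 0/1; item
marginals are equiprobable rather than skewed as real symptom items are;
nonresponse, snowball-sampling network structure and within-country
regional heterogeneity are out of scope. Consequently, passing tests show
that the *pipeline* behaves correctly under the assumed structure — not
that real survey data satisfy that structure. Composite scores built from
discretized items are attenuated relative to the latent traits, so
standardized coefficients estimated from scored scales shrink toward zero
by roughly the scales' reliabilities; recovery tests therefore assert
unbiasedness on the latent design and sign-plus-shrinkage on the scored
scales.

## Open defaults

Where the source material is silent the package fixes a value once and
documents it here: latent trait means/s.d. 0/1; the 10 post-traumatic
stress items treated as a generic 10-item subscale (the exact checklist
subset is unspecified); the life-stress composite summed over seven 1–4
items (range 7–28); youngest-child ages 1–10 with geometrically decreasing
weights; income as a discretized normal on a 1–10 ordinal scale; the
demographic prevalence tables in `country_preset()`.

# Problem sizes used by the tests and scripts

Desk-scale checks use \(p \le 8\) factors and \(R \le 50\) repeats:
the engine-equivalence suite runs 50 random instances at \(n \le 200,
p \le 6\); selection consistency uses \(p = 8\), \(R = 20\), 20 datasets
per sample size; transfer checks use \(n = 800\), \(R = 25\), 10 generator
seeds; moderation type-I error uses 200 replicates at \(n = 400\);
calibration checks run at \(n\) up to 50,000. The `analysis/` scripts run
the full 15-factor search at \(R = 50\) (a few minutes per country on one
CPU); \(R = 200\) reproduces the full design.

# Known limitations

* Winner percentages depend on the repeat count's granularity (5% at
  \(R = 20\)).
* The gram engine squares the design's condition number; for the
  standardized, well-conditioned designs used here that is harmless (the
  naive SVD path is the cross-check), but pathologically collinear designs
  should use `engine = "naive"`.
* The moderation analysis tests interactions on scored scales;
  measurement attenuation shrinks interaction coefficients more strongly
  than main effects, so configured interaction magnitudes below ~0.05 are
  not reliably detectable at realistic sample sizes.
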