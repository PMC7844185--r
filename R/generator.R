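# Synthetic multi-country cohort generator.
#
# A cohort is one row per respondent: demographics drawn from country-specific
# prevalence maps, latent psychological traits, Likert item responses sharing
# those traits at calibrated inter-item correlations, and a latent mental
# health outcome driven by configured standardized effects. Every random block
# draws from its own named substream of the global seed.

# scale catalog used by both the generator and the scoring module ------------
.scale_specs <- list(
  mental_health      = list(k = 27L, levels = 5L, alpha = 0.96),
  resilience         = list(k = 14L, levels = 5L, alpha = 0.85),
  life_stress        = list(k = 7L,  levels = 4L, alpha = 0.82),
  family_conflict    = list(k = 6L,  levels = 5L, alpha = 0.85),
  father_involvement = list(k = 20L, levels = 5L, alpha = 0.89)
)
.mh_subscale_sizes <- c(somatization = 6L, depression = 5L,
                        anxiety = 6L, ptsd = 10L)

item_cols <- function(scale) {
  k <- .scale_specs[[scale]]$k
  sprintf("%s_%02d", scale, seq_len(k))
}

#' Build a generator configuration
#'
#' All parameters of the synthetic-cohort model in one validated object:
#' sample size, categorical prevalence maps, latent trait moments, target
#' inter-item correlations per scale (derived from the scales' reliability
#' targets), standardized true effects on the latent outcome, interaction
#' effects, residual noise, and the general-factor loading that controls how
#' strongly the four symptom subscales correlate.
#'
#' @param country_label one of "CN", "IT", "NL".
#' @param n number of respondents.
#' @param seed integer global seed; expanded into per-block substreams.
#' @param categorical_prevalences named list: factor -> named probability
#'   vector over its levels (each summing to 1).
#' @param continuous_params named list: scale -> c(mean, sd) of the latent
#'   trait (defaults 0/1).
#' @param item_correlations named list: scale -> target observed inter-item
#'   correlation; defaults are calibrated from the scales' target alphas.
#' @param true_betas named numeric: standardized effect of each design term on
#'   the latent outcome.
#' @param interaction_betas named numeric: "a:b" -> effect of the centered
#'   product of terms a and b.
#' @param noise_sd residual standard deviation of the latent outcome.
#' @param subscale_loading general-factor loading shared by the four symptom
#'   subscale factors, in (0, 1].
#' @param jobchange_work_corr latent correlation between the job-change
#'   propensity and the work-stress trait.
#' @return an object of class `generator_config`.
#' @seealso [country_preset()], [generate_cohort()]
#' @export
generator_config <- function(country_label, n, seed = 1L,
                             categorical_prevalences,
                             continuous_params = list(),
                             item_correlations = list(),
                             true_betas = numeric(),
                             interaction_betas = numeric(),
                             noise_sd = 1,
                             subscale_loading = sqrt(0.95),
                             jobchange_work_corr = 0.42) {
  if (!country_label %in% c("CN", "IT", "NL"))
    stop_invalid("unknown country label: ", country_label)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_invalid("n must be a positive integer")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop_invalid("noise_sd must be > 0")
  if (subscale_loading <= 0 || subscale_loading > 1)
    stop_invalid("subscale_loading must be in (0, 1]")
  for (f in names(categorical_prevalences))
    assert_prob_map(categorical_prevalences[[f]], f)

  ic <- lapply(.scale_specs, function(s)
    calibrate_item_correlation(s$alpha, s$k))
  ic[names(item_correlations)] <- item_correlations
  for (r in unlist(ic))
    if (r < 0 || r >= 1) stop_invalid("item correlations must lie in [0, 1)")

  cp <- list()
  for (sc in names(.scale_specs)) cp[[sc]] <- c(0, 1)
  cp[names(continuous_params)] <- continuous_params

  structure(list(
    country_label = country_label,
    n = as.integer(n),
    seed = as.integer(seed),
    categorical_prevalences = categorical_prevalences,
    continuous_params = cp,
    item_correlations = ic,
    true_betas = true_betas,
    interaction_betas = interaction_betas,
    noise_sd = noise_sd,
    subscale_loading = subscale_loading,
    jobchange_work_corr = jobchange_work_corr,
    schema_version = "1.0"
  ), class = "generator_config")
}

#' Country presets for the three study cohorts
#'
#' Fully populated generator configurations emulating the Chinese, Italian
#' and Dutch survey cohorts: default sample sizes 922 / 641 / 900,
#' grandparental child-care support prevalence 53.6% / 18.3% / 9.4%, and
#' country-specific standardized true effects whose signs follow the
#' countries' reported risk/protective factor profiles (stress and family
#' conflict harmful and resilience protective everywhere; grandparental
#' support, marriage and more children protective in China with high
#' education/income and poor physical health as risks; younger age and poor
#' physical health as risks in Italy; high education and unemployment as
#' risks in the Netherlands).
#'
#' @param country_label "CN", "IT" or "NL".
#' @param n sample size override; defaults to the cohort's size.
#' @param seed global seed.
#' @return a [generator_config()] object.
#' @export
country_preset <- function(country_label, n = NULL, seed = 1L) {
  if (!is.character(country_label) || length(country_label) != 1L ||
      !country_label %in% c("CN", "IT", "NL"))
    stop_invalid("unknown country label: ",
                 paste(country_label, collapse = ","))
  def_n <- c(CN = 922L, IT = 641L, NL = 900L)[[country_label]]

  prev <- switch(country_label,
    CN = list(
      age = c("18-30" = 0.15, "30-35" = 0.35, "35-40" = 0.30, "40-60" = 0.20),
      marital = c(married = 0.95, divorced_other = 0.05),
      education = c(college_below = 0.30, university = 0.50, postgraduate = 0.20),
      employment = c(employed = 0.95, unemployed = 0.05),
      physical_health = c(poor = 0.10, fine = 0.40, good = 0.50),
      grandparental_support = c(no = 0.464, yes = 0.536),
      n_children = c("1" = 0.60, "2" = 0.33, "3" = 0.05, "4" = 0.02),
      age_youngest = NULL),
    IT = list(
      age = c("18-30" = 0.05, "30-35" = 0.20, "35-40" = 0.35, "40-60" = 0.40),
      marital = c(married = 0.88, divorced_other = 0.12),
      education = c(college_below = 0.45, university = 0.35, postgraduate = 0.20),
      employment = c(employed = 0.65, unemployed = 0.35),
      physical_health = c(poor = 0.08, fine = 0.42, good = 0.50),
      grandparental_support = c(no = 0.817, yes = 0.183),
      n_children = c("1" = 0.45, "2" = 0.44, "3" = 0.09, "4" = 0.02),
      age_youngest = NULL),
    NL = list(
      age = c("18-30" = 0.10, "30-35" = 0.30, "35-40" = 0.35, "40-60" = 0.25),
      marital = c(married = 0.90, divorced_other = 0.10),
      education = c(college_below = 0.35, university = 0.45, postgraduate = 0.20),
      employment = c(employed = 0.80, unemployed = 0.20),
      physical_health = c(poor = 0.05, fine = 0.35, good = 0.60),
      grandparental_support = c(no = 0.906, yes = 0.094),
      n_children = c("1" = 0.35, "2" = 0.50, "3" = 0.12, "4" = 0.03),
      age_youngest = NULL))
  # youngest child ages 1..10, weighted toward younger children
  ay <- 0.5^(seq(0, 4.5, by = 0.5)); ay <- ay / sum(ay)
  prev$age_youngest <- setNames(ay, as.character(1:10))

  shared <- c(life_stress = 0.15, work_stress = 0.15, family_conflict = 0.20,
              resilience = -0.25)
  betas <- switch(country_label,
    CN = c(shared,
           grandparental_support = -0.10,
           "marital:divorced_other" = 0.10,   # married protective
           n_children = -0.10,
           "education:university" = 0.08,
           "education:postgraduate" = 0.12,
           income = 0.10,
           "physical_health:fine" = -0.10,    # reference: poor
           "physical_health:good" = -0.20),
    IT = c(shared,
           "age:30-35" = -0.08,               # reference: 18-30 (highest risk)
           "age:35-40" = -0.12,
           "age:40-60" = -0.15,
           "physical_health:fine" = -0.12,
           "physical_health:good" = -0.22),
    NL = c(shared,
           "education:university" = 0.08,
           "education:postgraduate" = 0.14,
           "employment:unemployed" = 0.12))
  inter <- switch(country_label,
    CN = c("resilience:work_stress" = -0.08),
    IT = numeric(),
    NL = c("resilience:life_stress" = -0.08,
           "resilience:work_stress" = -0.08))

  generator_config(country_label, n = n %||% def_n, seed = seed,
                   categorical_prevalences = prev,
                   true_betas = betas, interaction_betas = inter)
}

#' Generate correlated ordinal Likert items from a latent trait
#'
#' Each item is a discretized Gaussian deviate sharing the standardized
#' latent trait: item_latent = sqrt(rho_l) * trait + sqrt(1 - rho_l) * noise,
#' cut at fixed equiprobable thresholds into the ordinal range. The latent
#' sharing rho_l is chosen (by numerical inversion of the discretization
#' attenuation) so that the expected pairwise correlation of the *ordinal*
#' items equals `rho`.
#'
#' @param latent numeric vector of standardized trait values (one per row).
#' @param k_items number of items to generate.
#' @param rho target pairwise inter-item correlation on the ordinal scale,
#'   in [0, 1).
#' @param levels contiguous integer vector of admissible responses,
#'   e.g. `1:5`.
#' @param seed integer seed (deterministic output for identical inputs).
#' @return integer matrix `length(latent)` x `k_items` with values in
#'   `levels`.
#' @export
generate_items_from_trait <- function(latent, k_items, rho, levels, seed) {
  if (length(latent) == 0) stop_invalid("latent trait vector is empty")
  if (rho < 0 || rho >= 1) stop_invalid("rho must lie in [0, 1)")
  if (!all(diff(levels) == 1L)) stop_invalid("levels must be contiguous")
  rho_l <- latent_rho_for_observed(rho, length(levels))
  thr <- ordinal_thresholds(length(levels))
  n <- length(latent)
  set.seed(seed)
  eps <- matrix(rnorm(n * k_items), n, k_items)
  z <- sqrt(rho_l) * latent + sqrt(1 - rho_l) * eps
  items <- matrix(findInterval(z, thr) + levels[1L], n, k_items)
  storage.mode(items) <- "integer"
  items
}

# sample a categorical column from a named prevalence vector ------------------
sample_levels <- function(n, prev) {
  names(prev)[findInterval(runif(n), cumsum(prev), left.open = TRUE) + 1L]
}

std01 <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a synthetic survey cohort
#'
#' Draws demographics from the configured prevalence maps, latent traits for
#' every multi-item scale, a job-change propensity correlated with the
#' work-stress trait, and a latent mental-health outcome
#' \eqn{y^* = \sum_f \beta_f x_f + \sum \beta_{ab} x_a x_b + \epsilon},
#' where the x's are standardized factor values. The 27 mental-health items
#' are produced from the standardized outcome through four correlated
#' subscale factors (somatization / depression / anxiety / post-traumatic
#' stress roles) sharing one general factor; all other scales' items share
#' their own trait at the calibrated inter-item correlation.
#'
#' The returned table carries the generating truth (latent outcome, traits,
#' standardized design columns) in `attr(, "latent")` for calibration and
#' recovery diagnostics.
#'
#' @param config a [generator_config()].
#' @return a `data.frame` cohort table (one row per respondent) with
#'   demographics and all raw item columns.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  seed <- config$seed
  prev <- config$categorical_prevalences

  demo <- with_substream(seed, "demographics", {
    data.frame(
      respondent_id = sprintf("%s_%06d", config$country_label, seq_len(n)),
      country = config$country_label,
      role = "mother",
      age = sample_levels(n, prev$age),
      marital = sample_levels(n, prev$marital),
      education = sample_levels(n, prev$education),
      employment = sample_levels(n, prev$employment),
      physical_health = sample_levels(n, prev$physical_health),
      income = findInterval(runif(n),
                            pnorm(seq(1.5, 9.5), mean = 6, sd = 2.2)) + 1L,
      n_children = as.integer(sample_levels(n, prev$n_children)),
      age_youngest = as.integer(sample_levels(n, prev$age_youngest)),
      grandparental_support =
        as.integer(sample_levels(n, prev$grandparental_support) == "yes"),
      stringsAsFactors = FALSE
    )
  })

  # latent traits, one substream each
  traits <- list()
  for (sc in c("resilience", "life_stress", "family_conflict",
               "father_involvement")) {
    p <- config$continuous_params[[sc]]
    traits[[sc]] <- with_substream(seed, paste0("trait_", sc),
                                   rnorm(n, p[1], p[2]))
  }
  traits$work_stress <- with_substream(seed, "trait_work_stress", rnorm(n))

  # job-change propensity shares the work-stress trait
  rho_jw <- config$jobchange_work_corr
  traits$job_change <- with_substream(seed, "trait_job_change",
    rho_jw * traits$work_stress + sqrt(1 - rho_jw^2) * rnorm(n))

  # standardized design columns used by the structural equation -------------
  xs <- list(
    resilience = std01(traits$resilience),
    life_stress = std01(traits$life_stress),
    work_stress = std01(traits$work_stress),
    job_change_index = std01(traits$job_change),
    family_conflict = std01(traits$family_conflict),
    father_involvement = std01(traits$father_involvement),
    grandparental_support = std01(demo$grandparental_support),
    income = std01(demo$income),
    n_children = std01(demo$n_children),
    age_youngest = std01(demo$age_youngest)
  )
  for (f in c("age", "marital", "education", "employment", "physical_health")) {
    lv <- names(prev[[f]])
    for (l in lv[-1L])                      # first level is the reference
      xs[[paste0(f, ":", l)]] <- std01(as.integer(demo[[f]] == l))
  }

  y_star <- rep(0, n)
  for (term in names(config$true_betas)) {
    if (is.null(xs[[term]]))
      stop_invalid("true_betas names unknown design term: ", term)
    y_star <- y_star + config$true_betas[[term]] * xs[[term]]
  }
  for (term in names(config$interaction_betas)) {
    ab <- strsplit(term, ":", fixed = TRUE)[[1L]]
    if (length(ab) != 2L || is.null(xs[[ab[1]]]) || is.null(xs[[ab[2]]]))
      stop_invalid("interaction_betas names unknown pair: ", term)
    y_star <- y_star +
      config$interaction_betas[[term]] * xs[[ab[1]]] * xs[[ab[2]]]
  }
  y_star <- y_star +
    with_substream(seed, "outcome_noise", rnorm(n, 0, config$noise_sd))

  # item blocks --------------------------------------------------------------
  cohort <- demo
  g <- std01(y_star)   # general psychopathology factor

  cs <- calibrate_subscale_structure(
    alpha_from_rho(config$item_correlations$mental_health, 27L),
    .mh_subscale_sizes, config$subscale_loading,
    .scale_specs$mental_health$levels)
  lam <- config$subscale_loading
  sub_f <- with_substream(seed, "mh_subscale_factors", {
    u <- matrix(rnorm(n * 4L), n, 4L)
    lam * g + sqrt(1 - lam^2) * u
  })
  mh <- matrix(NA_integer_, n, 27L)
  idx <- 1L
  for (s in seq_along(.mh_subscale_sizes)) {
    ks <- .mh_subscale_sizes[[s]]
    mh[, idx:(idx + ks - 1L)] <- generate_items_from_trait(
      sub_f[, s], ks, cs$r_within_obs, 1:5,
      substream_seed(seed, paste0("items_mh_", s)))
    idx <- idx + ks
  }
  colnames(mh) <- item_cols("mental_health")
  cohort <- cbind(cohort, mh)

  for (sc in c("resilience", "life_stress", "family_conflict",
               "father_involvement")) {
    spec <- .scale_specs[[sc]]
    m <- generate_items_from_trait(std01(traits[[sc]]), spec$k,
                                   config$item_correlations[[sc]],
                                   seq_len(spec$levels),
                                   substream_seed(seed, paste0("items_", sc)))
    colnames(m) <- item_cols(sc)
    cohort <- cbind(cohort, m)
  }

  # single work-stress item, 1..10 equiprobable cut of its trait
  thr10 <- ordinal_thresholds(10L)
  cohort$work_stress <- as.integer(
    findInterval(std01(traits$work_stress), thr10) + 1L)

  # 13 binary job-change indicators sharing the job-change propensity
  jc_load <- 0.7
  jc <- with_substream(seed, "items_job_change", {
    e <- matrix(rnorm(n * 13L), n, 13L)
    z <- jc_load * std01(traits$job_change) + sqrt(1 - jc_load^2) * e
    matrix(as.integer(z > qnorm(1 - 0.25)), n, 13L)
  })
  colnames(jc) <- sprintf("job_change_%02d", 1:13)
  cohort <- cbind(cohort, jc)

  attr(cohort, "latent") <- c(list(y_star = y_star), xs)
  attr(cohort, "config") <- config
  cohort
}

#' Factors carrying a nonzero true effect in a generator configuration
#'
#' Maps the configured `true_betas` term names (dummy terms like
#' `"education:university"` collapse to their factor) to the catalog factor
#' subset that actually generates the outcome — the configuration's "true
#' model".
#'
#' @param config a [generator_config()].
#' @return character vector of factor names.
#' @export
true_factors <- function(config) {
  terms <- names(config$true_betas)[config$true_betas != 0]
  unique(vapply(strsplit(terms, ":", fixed = TRUE), `[[`, character(1), 1L))
}

#' Write / read a cohort table as UTF-8 CSV with the canonical column order
#' @param cohort a cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort` returns the cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Serialize / restore a generator configuration (versioned JSON schema)
#' @param config a [generator_config()].
#' @param path file path.
#' @return `read_generator_config` returns the restored config.
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  # keep level/term names: named vectors become JSON objects, not arrays
  x$categorical_prevalences <- lapply(x$categorical_prevalences, as.list)
  x$continuous_params <- lapply(x$continuous_params, as.list)
  x$true_betas <- as.list(x$true_betas)
  x$interaction_betas <- as.list(x$interaction_betas)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  generator_config(x$country_label, x$n, x$seed,
                   categorical_prevalences =
                     lapply(x$categorical_prevalences, unlist),
                   continuous_params = lapply(x$continuous_params, unlist),
                   item_correlations = lapply(x$item_correlations, unlist),
                   true_betas = unlist(x$true_betas) %||% numeric(),
                   interaction_betas = unlist(x$interaction_betas) %||% numeric(),
                   noise_sd = x$noise_sd,
                   subscale_loading = x$subscale_loading,
                   jobchange_work_corr = x$jobchange_work_corr)
}
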