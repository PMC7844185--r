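# Robust standardized refits of the winning models, descriptive country
# comparisons, and the resilience moderation analysis.

#' Standardize outcome and continuous design columns
#'
#' Scales the outcome and every continuous predictor to mean 0, s.d. 1
#' (n-1 denominator); 0/1 dummy columns are left untouched so categorical
#' coefficients remain level contrasts.
#'
#' @param scored a scored cohort.
#' @param catalog a [factor_catalog()].
#' @param factors character vector of factors to include.
#' @param outcome outcome column name.
#' @return list with `y` (standardized outcome), `X` (design matrix without
#'   intercept), `is_dummy` flags, and the centering/scaling parameters.
#' @export
standardize <- function(scored, catalog, factors, outcome = "mental_health") {
  design <- build_design_matrix(scored, catalog[factors])
  X <- design$X[, -1L, drop = FALSE]
  is_dummy <- logical(ncol(X))
  centers <- scales <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    f <- factors[vapply(factors, function(ff)
      j %in% (design$blocks[[ff]] - 1L), logical(1))]
    kind <- catalog[[f]]$kind
    if (kind %in% c("binary", "categorical")) {
      is_dummy[j] <- TRUE
      centers[j] <- 0; scales[j] <- 1
    } else {
      s <- sd(X[, j])
      if (!is.finite(s) || s == 0)
        stop_invalid("continuous predictor is constant: ", colnames(X)[j])
      centers[j] <- mean(X[, j]); scales[j] <- s
      X[, j] <- (X[, j] - centers[j]) / s
    }
  }
  ys <- sd(scored[[outcome]])
  if (!is.finite(ys) || ys == 0) stop_invalid("outcome is constant")
  list(y = (scored[[outcome]] - mean(scored[[outcome]])) / ys,
       X = X, is_dummy = is_dummy, centers = centers, scales = scales,
       y_center = mean(scored[[outcome]]), y_scale = ys)
}

#' Robust (HC3) OLS fit summary
#'
#' Ordinary least squares point estimates with heteroskedasticity-consistent
#' HC3 sandwich standard errors, Wald z tests, and the plain OLS adjusted
#' R-squared.
#'
#' @param y outcome vector.
#' @param X design matrix without intercept (added internally).
#' @return object of class `fit_summary`: `data.frame` of per-term estimate,
#'   robust SE, z, p; with `adj_r_squared` and `n` attributes.
#' @export
robust_fit <- function(y, X) {
  X <- as.matrix(X)
  if (ncol(X) && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    drop_idx <- qrX$pivot[seq.int(qrX$rank + 1L, ncol(X) + 1L)] - 1L
    stop_invalid("design is rank deficient; collinear column(s): ",
                 paste(colnames(X)[drop_idx], collapse = ", "))
  }
  # design column names may contain ':' (dummy labels); fit under safe names
  terms_out <- c("(Intercept)", colnames(X))
  Xs <- X
  if (ncol(X)) colnames(Xs) <- paste0(".t", seq_len(ncol(X)))
  df <- data.frame(.y = y, Xs, check.names = FALSE)
  fit <- lm(.y ~ ., data = df)
  vc <- sandwich::vcovHC(fit, type = "HC3")
  dimnames(vc) <- list(terms_out, terms_out)
  est <- coef(fit)
  se <- sqrt(diag(vc))
  z <- est / se
  out <- data.frame(term = terms_out, estimate = unname(est),
                    robust_se = unname(se), z = unname(z),
                    p = unname(2 * pnorm(-abs(z))),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("fit_summary", "data.frame"),
            adj_r_squared = summary(fit)$adj.r.squared,
            n = length(y), vcov = vc, lm_fit = fit)
}

#' Robust standardized refit of a winning model (regression table analog)
#'
#' Standardizes outcome and continuous predictors, then applies
#' [robust_fit()] to the model's factor subset.
#'
#' @param scored a scored cohort.
#' @param catalog a [factor_catalog()].
#' @param factors included factor names (the winning subset).
#' @param outcome outcome column name.
#' @return a `fit_summary`.
#' @export
fit_winning_model <- function(scored, catalog, factors,
                              outcome = "mental_health") {
  sz <- standardize(scored, catalog, factors, outcome)
  robust_fit(sz$y, sz$X)
}

#' Coefficient export with non-selected factors fixed to zero
#'
#' Long-format table (country, term, beta, selected) over the FULL catalog:
#' terms of factors not in the winning model are written with beta 0, so
#' country coefficient displays are directly comparable.
#'
#' @param fit a `fit_summary` from [fit_winning_model()].
#' @param catalog a [factor_catalog()].
#' @param country country label.
#' @return `data.frame` with one row per catalog design term.
#' @export
coefficient_export <- function(fit, catalog, country) {
  all_terms <- unlist(lapply(names(catalog), function(f) {
    fa <- catalog[[f]]
    if (fa$kind == "categorical") paste0(f, ":", fa$levels[-1L]) else f
  }))
  est <- setNames(fit$estimate, fit$term)
  data.frame(
    country = country,
    term = all_terms,
    beta = ifelse(all_terms %in% names(est), est[all_terms], 0),
    selected = all_terms %in% names(est),
    row.names = NULL
  )
}

#' Moderation analysis with centered product terms and simple slopes
#'
#' Augments the base model with interactions between a moderator and focal
#' stress terms (all standardized, so products are centered), fits with HC3
#' robust errors, and reports simple slopes of each focal term at moderator
#' values -1, 0 and +1 s.d., with delta-method robust SEs.
#'
#' @param scored a scored cohort.
#' @param catalog a [factor_catalog()].
#' @param base_factors factors of the base model (must contain moderator and
#'   focal terms).
#' @param moderator moderating factor name (continuous), e.g. "resilience".
#' @param focal_terms continuous focal factor names, e.g.
#'   `c("life_stress", "work_stress")`.
#' @param outcome outcome column name.
#' @return object of class `moderation_result`: list with `fit` (the full
#'   `fit_summary`), `interactions` (rows of the interaction terms) and
#'   `simple_slopes`.
#' @export
moderation_analysis <- function(scored, catalog, base_factors, moderator,
                                focal_terms, outcome = "mental_health") {
  stopifnot(moderator %in% base_factors, all(focal_terms %in% base_factors))
  for (f in c(moderator, focal_terms))
    if (catalog[[f]]$kind != "continuous")
      stop_invalid("moderation terms must be continuous factors: ", f)
  sz <- standardize(scored, catalog, base_factors, outcome)
  X <- sz$X
  for (ft in focal_terms)
    X <- cbind(X, setNames(
      data.frame(X[, moderator] * X[, ft]),
      paste0(moderator, ":", ft)))
  X <- as.matrix(X)
  fit <- robust_fit(sz$y, X)
  vc <- attr(fit, "vcov")
  inter <- fit[fit$term %in% paste0(moderator, ":", focal_terms), ]
  slopes <- do.call(rbind, lapply(focal_terms, function(ft) {
    it <- paste0(moderator, ":", ft)
    bi <- c(fit$estimate[fit$term == ft], fit$estimate[fit$term == it])
    idx <- match(c(ft, it), rownames(vc))
    do.call(rbind, lapply(c(-1, 0, 1), function(mlev) {
      slope <- bi[1] + mlev * bi[2]
      se <- sqrt(vc[idx[1], idx[1]] + mlev^2 * vc[idx[2], idx[2]] +
                   2 * mlev * vc[idx[1], idx[2]])
      data.frame(focal = ft, moderator_sd = mlev, slope = slope,
                 robust_se = se, z = slope / se,
                 p = 2 * pnorm(-abs(slope / se)))
    }))
  }))
  structure(list(fit = fit, interactions = inter, simple_slopes = slopes),
            class = "moderation_result")
}

#' Descriptive comparison of country cohorts
#'
#' Means and standard deviations with one-way ANOVA F tests for continuous
#' variables; level counts and percentages with Pearson chi-square tests
#' (no continuity correction) for categorical variables.
#'
#' @param cohorts named list: country -> scored cohort.
#' @param continuous_vars,categorical_vars variable names; defaults cover the
#'   derived scores and the demographic factors.
#' @return `data.frame` with one row per variable (and per level for
#'   categoricals): per-country descriptives, test statistic and p value.
#' @export
group_comparison_table <- function(cohorts,
    continuous_vars = c("mental_health", "resilience", "life_stress",
                        "work_stress", "job_change_index", "family_conflict",
                        "father_involvement", "income", "n_children",
                        "age_youngest"),
    categorical_vars = c("age", "marital", "education", "employment",
                         "physical_health", "grandparental_support")) {
  if (length(cohorts) < 2L) stop_invalid("need at least 2 groups")
  countries <- names(cohorts)
  rows <- list()
  for (v in continuous_vars) {
    vals <- lapply(cohorts, function(d) d[[v]])
    g <- factor(rep(countries, vapply(vals, length, integer(1))))
    x <- unlist(vals, use.names = FALSE)
    cell <- vapply(vals, function(u)
      sprintf("%.2f (%.2f)", mean(u), sd(u)), character(1))
    if (all(vapply(vals, function(u) sd(u) == 0, logical(1))) ||
        sd(x) == 0) {
      stat <- NA_real_; p <- NA_real_
    } else {
      a <- anova(aov(x ~ g))
      stat <- a$`F value`[1]; p <- a$`Pr(>F)`[1]
    }
    rows[[v]] <- data.frame(variable = v, level = "",
                            t(cell), test = "ANOVA F",
                            statistic = stat, p = p,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  for (v in categorical_vars) {
    tabs <- lapply(cohorts, function(d) table(factor(d[[v]])))
    lv <- sort(unique(unlist(lapply(tabs, names))))
    counts <- vapply(cohorts, function(d)
      as.integer(table(factor(d[[v]], levels = lv))), integer(length(lv)))
    counts <- matrix(counts, nrow = length(lv),
                     dimnames = list(lv, countries))
    if (length(lv) < 2L) {
      stat <- NA_real_; p <- NA_real_
    } else {
      cs <- suppressWarnings(chisq.test(counts, correct = FALSE))
      stat <- unname(cs$statistic); p <- cs$p.value
    }
    for (l in lv) {
      cell <- vapply(countries, function(cc) {
        n <- counts[l, cc]
        sprintf("%d (%.1f%%)", n, 100 * n / sum(counts[, cc]))
      }, character(1))
      rows[[paste(v, l)]] <- data.frame(
        variable = v, level = l, t(cell), test = "chi-square",
        statistic = stat, p = p,
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  names(out)[3:(2 + length(countries))] <- countries
  out
}
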