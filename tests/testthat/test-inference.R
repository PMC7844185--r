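scored_fixture <- function(n = 400, seed = 1, cc = "NL") {
  score_cohort(generate_cohort(country_preset(cc, n = n, seed = seed)))
}

test_that("standardization centers continuous terms and spares dummies", {
  co <- scored_fixture(300, 7)
  cat_ <- factor_catalog()
  sz <- standardize(co, cat_, c("resilience", "education", "work_stress"))
  expect_equal(mean(sz$y), 0, tolerance = 1e-12)
  expect_equal(sd(sz$y), 1, tolerance = 1e-12)
  expect_equal(mean(sz$X[, "resilience"]), 0, tolerance = 1e-12)
  expect_equal(sd(sz$X[, "resilience"]), 1, tolerance = 1e-12)
  expect_true(all(sz$X[, "education:university"] %in% 0:1))
  expect_true(all(sz$is_dummy[colnames(sz$X) != "resilience" &
                                colnames(sz$X) != "work_stress"]))
  co$resilience <- 50
  expect_error(standardize(co, cat_, "resilience"), "constant")
})

test_that("standardized coefficients solve the normal equations", {
  # y identical to x: beta = 1 after standardization
  set.seed(15)
  x <- rnorm(100)
  f <- suppressWarnings(robust_fit((x - mean(x)) / sd(x),
                  matrix((x - mean(x)) / sd(x), dimnames = list(NULL, "x"))))
  expect_equal(f$estimate[f$term == "x"], 1, tolerance = 1e-10)

  # two correlated predictors: beta from the 2x2 normal equations by hand
  n <- 5000
  set.seed(16)
  x1 <- rnorm(n); x2 <- 0.6 * x1 + 0.8 * rnorm(n)
  y <- 0.5 * x1 + 0.25 * x2 + rnorm(n)
  zs <- function(v) (v - mean(v)) / sd(v)
  X <- cbind(x1 = zs(x1), x2 = zs(x2))
  fit <- robust_fit(zs(y), X)
  r12 <- cor(x1, x2); r1y <- cor(x1, y); r2y <- cor(x2, y)
  b_hand <- solve(matrix(c(1, r12, r12, 1), 2), c(r1y, r2y))
  expect_equal(fit$estimate[match(c("x1", "x2"), fit$term)], b_hand,
               tolerance = 1e-10)
})

test_that("scale change of a predictor leaves its standardized beta intact", {
  co <- scored_fixture(350, 21)
  cat_ <- factor_catalog()
  f1 <- fit_winning_model(co, cat_, c("resilience", "life_stress"))
  co2 <- co
  co2$life_stress <- co2$life_stress * 37.5
  f2 <- fit_winning_model(co2, cat_, c("resilience", "life_stress"))
  expect_equal(f1$estimate, f2$estimate, tolerance = 1e-10)
})

test_that("robust fit reports HC3 errors, Wald p and OLS adjusted R2", {
  # homoskedastic large-n: HC3 close to classical
  set.seed(23)
  n <- 4000
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- 0.4 * X[, 1] - 0.2 * X[, 2] + rnorm(n)
  fit <- robust_fit(y, X)
  lmfit <- lm(y ~ X)
  classical <- sqrt(diag(vcov(lmfit)))
  expect_true(all(abs(fit$robust_se / classical - 1) < 0.10))
  expect_equal(attr(fit, "adj_r_squared"), summary(lmfit)$adj.r.squared)
  # robust covariance agrees with the reference sandwich estimator
  ref <- sandwich::vcovHC(lmfit, type = "HC3")
  expect_equal(unname(attr(fit, "vcov")), unname(ref), tolerance = 1e-10)

  # perfect fit: adjusted R2 = 1
  yp <- as.numeric(2 + X %*% c(1, -1))
  fp <- suppressWarnings(robust_fit(yp, X))
  expect_equal(attr(fp, "adj_r_squared"), 1)

  # intercept-only: adjusted R2 = 0
  f0 <- robust_fit(rnorm(50), matrix(numeric(0), 50, 0))
  expect_equal(attr(f0, "adj_r_squared"), 0)

  # rank deficiency names the collinear column
  Xc <- cbind(X, dup = X[, 1])
  expect_error(robust_fit(y, Xc), "dup")
})

test_that("winning-model refit recovers configured effects on large cohorts", {
  cfg <- country_preset("NL", n = 20000, seed = 55)
  cfg$interaction_betas <- numeric()
  co <- score_cohort(generate_cohort(cfg))
  cat_ <- factor_catalog()

  # on the error-free (latent) design the standardized betas are unbiased:
  # robust_fit recovers every configured effect within 0.02
  lat <- attr(co, "latent")
  terms <- names(cfg$true_betas)
  Xl <- do.call(cbind, lat[terms]); colnames(Xl) <- terms
  fl <- robust_fit((lat$y_star - mean(lat$y_star)) / sd(lat$y_star), Xl)
  sy <- sd(lat$y_star)
  for (term in terms)
    expect_lt(abs(fl$estimate[fl$term == term] * sy - cfg$true_betas[[term]]),
              0.02)

  # on the scored scales the betas keep their sign but shrink toward zero
  # (Likert measurement attenuation)
  fit <- fit_winning_model(co, cat_, true_factors(cfg))
  for (term in c("resilience", "life_stress", "work_stress",
                 "family_conflict")) {
    est <- fit$estimate[fit$term == term]
    truth <- cfg$true_betas[[term]]
    expect_equal(sign(est), sign(truth))
    expect_lt(abs(est), abs(truth) * 1.02)
    expect_gt(abs(est), abs(truth) * 0.5)
  }
  expect_gt(attr(fit, "adj_r_squared"), 0.05)
})

test_that("coefficient export fixes non-selected factors to zero", {
  co <- scored_fixture(300, 9)
  cat_ <- factor_catalog()
  fit <- fit_winning_model(co, cat_, c("resilience", "education"))
  ex <- coefficient_export(fit, cat_, "NL")
  expect_equal(nrow(ex), 19L)       # every design term of the full catalog
  expect_true(all(ex$beta[!ex$selected] == 0))
  expect_equal(sum(ex$selected), 3L)  # resilience + 2 education dummies
  expect_equal(ex$beta[ex$term == "resilience"],
               fit$estimate[fit$term == "resilience"])
})

test_that("simple slopes obey the centering identity", {
  co <- scored_fixture(500, 33)
  cat_ <- factor_catalog()
  mod <- moderation_analysis(co, cat_,
                             c("resilience", "life_stress", "work_stress"),
                             "resilience", c("life_stress", "work_stress"))
  # at mean moderator the simple slope equals the focal main effect
  for (ft in c("life_stress", "work_stress")) {
    s0 <- mod$simple_slopes[mod$simple_slopes$focal == ft &
                              mod$simple_slopes$moderator_sd == 0, ]
    expect_equal(s0$slope, mod$fit$estimate[mod$fit$term == ft])
    sl <- mod$simple_slopes[mod$simple_slopes$focal == ft, ]
    b_int <- mod$fit$estimate[mod$fit$term == paste0("resilience:", ft)]
    expect_equal(diff(sl$slope), rep(b_int, 2), tolerance = 1e-12)
  }
  expect_error(
    moderation_analysis(co, cat_, c("resilience", "education"),
                        "resilience", "education"),
    "continuous")
})

test_that("country comparison reports ANOVA, chi-square and hand-checkable cells", {
  co1 <- scored_fixture(150, 41, "CN")
  co2 <- scored_fixture(150, 42, "IT")
  tab <- group_comparison_table(list(CN = co1, IT = co2))
  expect_true(all(c("variable", "CN", "IT", "statistic", "p") %in% names(tab)))
  expect_true(all(tab$p >= 0 & tab$p <= 1, na.rm = TRUE))

  # identical groups: F = 0 and chi-square = 0
  same <- group_comparison_table(list(A = co1, B = co1))
  expect_equal(max(same$statistic[same$test == "ANOVA F"]), 0,
               tolerance = 1e-12)
  expect_equal(max(same$statistic[same$test == "chi-square"]), 0,
               tolerance = 1e-12)

  # hand 2x2 table ((30,10),(10,30)): chi-square = sum (O-E)^2/E = 20
  g1 <- data.frame(v = rep(c("x", "y"), c(30, 10)))
  g2 <- data.frame(v = rep(c("x", "y"), c(10, 30)))
  out <- group_comparison_table(list(A = g1, B = g2),
                                continuous_vars = character(),
                                categorical_vars = "v")
  expect_equal(out$statistic[1], 20)
})
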