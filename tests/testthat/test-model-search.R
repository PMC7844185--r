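test_that("model enumeration covers every subset in canonical order", {
  expect_equal(length(enumerate_models(toy_catalog(3))), 8L)
  expect_equal(length(enumerate_models(structure(list(),
                                                class = "factor_catalog"))), 1L)
  ms <- enumerate_models(toy_catalog(4))
  expect_false(any(ms$mask[1, ]))                    # intercept-only first
  expect_equal(anyDuplicated(apply(ms$mask, 1, paste, collapse = "")), 0L)
  # mask-ascending order: factor j flips with period 2^(j-1)
  expect_equal(ms$mask[2, ], c(f1 = TRUE, f2 = FALSE, f3 = FALSE, f4 = FALSE))
  expect_equal(ms$mask[3, ], c(f1 = FALSE, f2 = TRUE, f3 = FALSE, f4 = FALSE))
})

test_that("design matrix uses reference dummy coding with disjoint blocks", {
  co <- score_cohort(generate_cohort(country_preset("CN", n = 60, seed = 2)))
  cat_ <- factor_catalog()
  d <- build_design_matrix(co, cat_)
  # 1 intercept + 10 single columns + (1 + 3 + 2 + 1 + 2) dummies = 20
  expect_equal(ncol(d$X), 20L)
  expect_equal(length(d$blocks$education), 2L)
  expect_equal(length(d$blocks$age), 3L)
  expect_equal(length(d$blocks$grandparental_support), 1L)
  all_idx <- unlist(d$blocks)
  expect_equal(anyDuplicated(all_idx), 0L)
  expect_false(1L %in% all_idx)                      # intercept outside blocks
  # unseen level errors
  co2 <- co; co2$education[1] <- "doctorate"
  expect_error(build_design_matrix(co2, cat_), "unseen level")
})

test_that("fold partitions are balanced, complete and seed-deterministic", {
  f <- make_fold_partition(900, 10, 1)
  expect_equal(as.integer(table(f)), rep(90L, 10))
  g <- make_fold_partition(23, 10, 5)
  expect_true(all(table(g) %in% 2:3))
  expect_equal(sum(table(g)), 23L)
  expect_identical(make_fold_partition(50, 7, 3), make_fold_partition(50, 7, 3))
  expect_false(identical(make_fold_partition(50, 7, 3),
                         make_fold_partition(50, 7, 4)))
  expect_error(make_fold_partition(5, 10, 1), "n must be >= k")
})

test_that("cv_rmse reproduces hand-worked fold fits", {
  # two-point OLS predicts the held-out rows exactly
  X <- cbind(1, c(0, 0, 1, 1))
  expect_equal(cv_rmse(c(0, 0, 2, 2), X, 1:2, c(1, 2, 1, 2)), 0,
               tolerance = 1e-12)
  # intercept-only, leave-one-out on y = (0, 2): each training mean is off by 2
  expect_equal(cv_rmse(c(0, 2), matrix(1, 2, 1), 1, c(1, 2)), 2)
  # saturated model attains the 0 lower bound
  set.seed(8)
  Xs <- cbind(1, rnorm(6))
  ys <- as.numeric(Xs %*% c(0.3, -1))
  expect_equal(cv_rmse(ys, Xs, 1:2, rep(1:3, 2)), 0, tolerance = 1e-10)
  expect_error(cv_rmse(1:4, cbind(1, 1:4), 1:2, c(1, 1)), "partition")
})

test_that("gram and naive engines agree within 1e-8 on random instances", {
  set.seed(101)
  for (i in 1:12) {
    n <- sample(25:120, 1)
    p <- sample(1:5, 1)
    inst <- toy_instance(n, p, true_cols = seq_len(min(2, p)), beta = 0.4,
                         noise_sd = 1, seed = 300 + i)
    models <- enumerate_models(toy_catalog(p))
    rg <- run_search_matrix(inst$y, inst$design, models,
                            cv_config(5, 3, seed = i, engine = "gram"))
    rn <- run_search_matrix(inst$y, inst$design, models,
                            cv_config(5, 3, seed = i, engine = "naive"))
    expect_lt(max(abs(rg$rmse - rn$rmse)), 1e-8)
    expect_identical(rg$winners, rn$winners)
  }
})

test_that("inverted orientation trains on one fold and validates on the rest", {
  inst <- toy_instance(60, 3, true_cols = 1, beta = 1, noise_sd = 0.5,
                       seed = 77)
  part <- make_fold_partition(60, 5, 9)
  std <- cv_rmse(inst$y, inst$design$X, 1:2, part, orientation = "standard")
  inv <- cv_rmse(inst$y, inst$design$X, 1:2, part, orientation = "invert")
  expect_true(is.finite(inv) && inv > 0)
  # training on 12 rows instead of 48 predicts worse on average
  expect_gt(inv, std * 0.9)
  models <- enumerate_models(toy_catalog(3))
  ri <- run_search_matrix(inst$y, inst$design, models,
                          cv_config(5, 4, seed = 2, engine = "gram",
                                    orientation = "invert"))
  expect_true(all(is.finite(ri$rmse)))
})

test_that("a noise-free truth is recovered in every repeat", {
  inst <- toy_instance(200, 6, true_cols = 1:3, beta = 0.5, noise_sd = 0,
                       seed = 5)
  models <- enumerate_models(toy_catalog(6))
  res <- run_search_matrix(inst$y, inst$design, models,
                           cv_config(10, 10, seed = 4))
  idx <- toy_model_index(models, 1:3)
  expect_equal(res$pct[idx], 100)
  top <- top_models_table(res, 3)
  expect_equal(top$model[1], idx)
  expect_equal(top$win_pct[1], 100)
  expect_true(all(diff(top$win_pct) <= 0))
})

test_that("an irrelevant predictor loses to the intercept-only model", {
  # pure-noise outcome, one candidate factor: out-of-sample the extra
  # parameter only adds variance, so the null model wins most repeats
  inst <- toy_instance(400, 1, true_cols = integer(), noise_sd = 1, seed = 13)
  models <- enumerate_models(toy_catalog(1))
  res <- run_search_matrix(inst$y, inst$design, models,
                           cv_config(10, 40, seed = 6))
  expect_gt(res$pct[1], 50)
})

test_that("winner percentages partition the repeats", {
  inst <- toy_instance(80, 4, true_cols = 1:2, beta = 0.3, seed = 21)
  models <- enumerate_models(toy_catalog(4))
  res <- run_search_matrix(inst$y, inst$design, models,
                           cv_config(5, 17, seed = 3))
  expect_equal(sum(res$pct), 100)
  expect_equal(sum(res$tally), 17L)
  expect_true(all(res$mean_rmse >= 0))
})

test_that("adding a true factor never hurts under zero noise", {
  inst <- toy_instance(150, 5, true_cols = 1:3, beta = 0.6, noise_sd = 0,
                       seed = 31)
  models <- enumerate_models(toy_catalog(5))
  part <- make_fold_partition(150, 10, 2)
  # nested chain {} < {1} < {1,2} < {1,2,3}: RMSEp non-increasing
  chain <- list(integer(), 1L, 1:2, 1:3)
  rmse <- vapply(chain, function(cc)
    cv_rmse(inst$y, inst$design$X, c(1L, cc + 1L), part), numeric(1))
  expect_true(all(diff(rmse) <= 1e-8))
  expect_equal(rmse[4], 0, tolerance = 1e-8)
})

test_that("identical cv configuration reproduces an identical search", {
  inst <- toy_instance(70, 3, true_cols = 1, beta = 0.5, seed = 55)
  models <- enumerate_models(toy_catalog(3))
  r1 <- run_search_matrix(inst$y, inst$design, models, cv_config(5, 6, seed = 8))
  r2 <- run_search_matrix(inst$y, inst$design, models, cv_config(5, 6, seed = 8))
  expect_identical(r1$rmse, r2$rmse)
  expect_identical(r1$winners, r2$winners)
})

test_that("rank-deficient training folds fall back to minimum-norm fits", {
  # duplicated column: X block is exactly collinear in every fold
  set.seed(91)
  x <- rnorm(40)
  X <- cbind(1, x, x)
  colnames(X) <- c("(Intercept)", "f1", "f2")
  y <- 0.5 * x + rnorm(40, 0, 0.1)
  part <- make_fold_partition(40, 5, 1)
  r <- cv_rmse(y, X, 1:3, part)
  expect_true(is.finite(r))
  # gram path handles it too and agrees
  design <- list(X = X, blocks = list(f1 = 2L, f2 = 3L))
  models <- enumerate_models(toy_catalog(2))
  rg <- run_search_matrix(y, design, models,
                          cv_config(5, 2, seed = 1, engine = "gram"))
  rn <- run_search_matrix(y, design, models,
                          cv_config(5, 2, seed = 1, engine = "naive"))
  expect_lt(max(abs(rg$rmse - rn$rmse)), 1e-6)
})

test_that("top-models table warns and truncates when k exceeds the model count", {
  inst <- toy_instance(50, 2, true_cols = 1, seed = 3)
  models <- enumerate_models(toy_catalog(2))
  res <- run_search_matrix(inst$y, inst$design, models, cv_config(5, 4, seed = 1))
  expect_warning(tab <- top_models_table(res, 10), "truncating")
  expect_equal(nrow(tab), 4L)
})
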