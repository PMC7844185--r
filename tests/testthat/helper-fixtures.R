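# Shared fixtures: tiny catalogs and matrix designs for the search engine.

# a catalog of p continuous pseudo-factors named f1..fp
toy_catalog <- function(p) {
  structure(setNames(lapply(seq_len(p), function(j)
    list(name = paste0("f", j), kind = "continuous")),
    paste0("f", seq_len(p))), class = "factor_catalog")
}

# matrix design for the toy catalog: intercept + one column per factor
toy_design <- function(X) {
  p <- ncol(X)
  Xd <- cbind(1, X)
  colnames(Xd) <- c("(Intercept)", paste0("f", seq_len(p)))
  list(X = Xd, blocks = as.list(setNames(seq_len(p) + 1L,
                                         paste0("f", seq_len(p)))))
}

# y = X[, true_cols] beta + noise on a fresh standard-normal design
toy_instance <- function(n, p, true_cols = integer(), beta = 0.5,
                         noise_sd = 1, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(if (length(true_cols))
    X[, true_cols, drop = FALSE] %*% rep(beta, length(true_cols))
    else rep(0, n)) + rnorm(n, 0, noise_sd)
  list(X = X, y = y, design = toy_design(X))
}

# index of the model whose mask includes exactly `cols` in a toy model set
toy_model_index <- function(models, cols) {
  target <- seq_along(models$factors) %in% cols
  which(apply(models$mask, 1, function(m) all(m == target)))
}

# a 3-row hand-made cohort exercising the inclusion filter
mixed_role_table <- function() {
  data.frame(
    respondent_id = c("a", "b", "c", "d"),
    role = c("mother", "father", "mother", "mother"),
    age = c("35-40", "30-35", "18-30", "30-35"),
    age_youngest = c(3L, 4L, 12L, 1L),
    stringsAsFactors = FALSE
  )
}
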