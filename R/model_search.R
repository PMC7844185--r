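# Exhaustive all-subsets regression search under repeated k-fold
# cross-validation, ranked by RMSE of prediction with winner tallies.

#' The candidate factor catalog of the maternal mental health analysis
#'
#' Fifteen candidate risk/protective factors: seven survey-derived
#' (resilience, pandemic life stress, pandemic work stress, job-change index,
#' family conflict, father involvement, grandparental support) and eight
#' demographic (marital status, maternal age band, education, employment,
#' physical health, household income, number of children, age of youngest
#' child). Categorical factors carry their levels and reference level and
#' enter the design as a dummy block.
#'
#' @return object of class `factor_catalog`: named list of factors with
#'   `name`, `kind` ("continuous", "binary" or "categorical"), and for
#'   categoricals `levels` (first level = reference).
#' @export
factor_catalog <- function() {
  fc <- function(name, kind, levels = NULL)
    list(name = name, kind = kind, levels = levels)
  structure(list(
    resilience = fc("resilience", "continuous"),
    life_stress = fc("life_stress", "continuous"),
    work_stress = fc("work_stress", "continuous"),
    job_change_index = fc("job_change_index", "continuous"),
    family_conflict = fc("family_conflict", "continuous"),
    father_involvement = fc("father_involvement", "continuous"),
    grandparental_support = fc("grandparental_support", "binary"),
    marital = fc("marital", "categorical", c("married", "divorced_other")),
    age = fc("age", "categorical", c("18-30", "30-35", "35-40", "40-60")),
    education = fc("education", "categorical",
                   c("college_below", "university", "postgraduate")),
    employment = fc("employment", "categorical", c("employed", "unemployed")),
    physical_health = fc("physical_health", "categorical",
                         c("poor", "fine", "good")),
    income = fc("income", "continuous"),
    n_children = fc("n_children", "continuous"),
    age_youngest = fc("age_youngest", "continuous")
  ), class = "factor_catalog")
}

#' Enumerate every subset of the factor catalog as a model set
#'
#' All 2^p inclusion masks over the p catalog factors, in canonical
#' mask-ascending order (model 1 is the intercept-only model; factor j flips
#' with period 2^(j-1)). Categorical factors enter or leave as whole blocks.
#'
#' @param catalog a [factor_catalog()] (or any named factor list).
#' @return object of class `model_set`: list with `mask` (2^p x p logical
#'   matrix) and `factors` (catalog names).
#' @export
enumerate_models <- function(catalog) {
  p <- length(catalog)
  if (p > 24L) stop_invalid("refusing to enumerate > 2^24 models")
  m <- 2L^p
  mask <- matrix(FALSE, m, max(p, 0L))
  if (p > 0L) {
    for (j in seq_len(p))
      mask[, j] <- rep(c(FALSE, TRUE), each = 2L^(j - 1L), length.out = m)
    colnames(mask) <- names(catalog)
  }
  structure(list(mask = mask, factors = names(catalog)),
            class = "model_set")
}

#' Number of models in a model set
#' @param x a `model_set`.
#' @param ... unused.
#' @export
length.model_set <- function(x) nrow(x$mask)

#' Human-readable formula string for an inclusion mask
#' @keywords internal
mask_formula <- function(mask, factors, outcome = "mental_health") {
  rhs <- if (any(mask)) paste(factors[mask], collapse = " + ") else "1"
  paste(outcome, "~", rhs)
}

#' Build the reference-coded design matrix for a scored cohort
#'
#' Continuous and binary factors pass through as single columns; categorical
#' factors expand to reference-level dummy blocks. The intercept is column 1.
#'
#' @param scored a scored cohort (see [score_cohort()]).
#' @param catalog a [factor_catalog()].
#' @return list with `X` (numeric matrix, intercept first), and `blocks`
#'   (named list mapping each factor to its column indices in `X`).
#' @export
build_design_matrix <- function(scored, catalog) {
  n <- nrow(scored)
  cols <- list(`(Intercept)` = rep(1, n))
  blocks <- list()
  for (f in names(catalog)) {
    fa <- catalog[[f]]
    if (!f %in% names(scored))
      stop_invalid("factor column missing from cohort: ", f)
    if (fa$kind %in% c("continuous", "binary")) {
      cols[[f]] <- as.numeric(scored[[f]])
      blocks[[f]] <- length(cols)
    } else {
      obs <- unique(as.character(scored[[f]]))
      unseen <- setdiff(obs, fa$levels)
      if (length(unseen))
        stop_invalid("unseen level(s) in factor '", f, "': ",
                     paste(unseen, collapse = ", "))
      idx <- integer()
      for (l in fa$levels[-1L]) {
        cols[[paste0(f, ":", l)]] <- as.numeric(scored[[f]] == l)
        idx <- c(idx, length(cols))
      }
      blocks[[f]] <- idx
    }
  }
  X <- do.call(cbind, cols)
  list(X = X, blocks = blocks)
}

#' Repeated-CV configuration
#' @param k number of folds (>= 2).
#' @param repeats number of cross-validation repeats (>= 1).
#' @param seed integer seed governing all fold partitions.
#' @param engine "gram" (compiled cross-product path) or "naive"
#'   (per-fold refit in R).
#' @param orientation "standard" trains on k-1 folds and predicts the held
#'   out fold; "invert" trains on a single fold and predicts the other k-1.
#' @return object of class `cv_config`.
#' @export
cv_config <- function(k = 10L, repeats = 200L, seed = 1L,
                      engine = c("gram", "naive"),
                      orientation = c("standard", "invert")) {
  if (k < 2L) stop_invalid("k must be >= 2")
  if (repeats < 1L) stop_invalid("repeats must be >= 1")
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), engine = match.arg(engine),
                 orientation = match.arg(orientation)),
            class = "cv_config")
}

#' Deterministic balanced fold assignment
#'
#' @param n number of rows (>= k).
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids 1..k; fold sizes differ by at most 1.
#' @export
make_fold_partition <- function(n, k, seed) {
  if (n < k) stop_invalid("n must be >= k")
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  folds <- rep(seq_len(k), times = sizes)
  with_substream(seed, "fold_partition", folds[sample.int(n)])
}

# partition matrix (n x R) shared across models / engines / transfer pairs
fold_matrix <- function(n, cv) {
  vapply(seq_len(cv$repeats),
         function(r) make_fold_partition(n, cv$k, cv$seed + r - 1L),
         integer(n))
}

# minimum-norm least squares (SVD pseudo-inverse), matching the gram engine's
# rank-deficient fallback
lstsq_minnorm <- function(X, y) {
  sv <- svd(X)
  tol <- max(dim(X)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  if (!any(pos)) return(rep(0, ncol(X)))
  sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
}

#' Cross-validated RMSE of prediction for one model
#'
#' For each fold, ordinary least squares is fitted on the remaining folds and
#' the held-out fold predicted; RMSEp is the square root of the mean of all n
#' held-out squared errors. With `orientation = "invert"` the roles are
#' swapped: the model is trained on the single fold and predicts the rest.
#'
#' @param y outcome vector.
#' @param X design matrix (intercept included as a column).
#' @param columns integer indices of the design columns the model uses
#'   (include the intercept column).
#' @param partition fold assignment vector covering all rows (1..k).
#' @param orientation see [cv_config()].
#' @return RMSEp (non-negative scalar).
#' @export
cv_rmse <- function(y, X, columns, partition,
                    orientation = c("standard", "invert")) {
  orientation <- match.arg(orientation)
  if (length(partition) != length(y))
    stop_invalid("partition must cover all rows")
  Xm <- X[, columns, drop = FALSE]
  sse <- 0
  for (f in sort(unique(partition))) {
    hold <- if (orientation == "standard") partition == f else partition != f
    if (sum(!hold) < 1L) stop_invalid("degenerate fold: empty training set")
    beta <- lstsq_minnorm(Xm[!hold, , drop = FALSE], y[!hold])
    pred <- Xm[hold, , drop = FALSE] %*% beta
    sse <- sse + sum((y[hold] - pred)^2)
  }
  denom <- if (orientation == "standard") length(y) else
    length(y) * (length(unique(partition)) - 1L)
  sqrt(sse / denom)
}

model_columns <- function(mask, blocks) {
  c(1L, unlist(blocks[mask], use.names = FALSE))
}

#' Run the exhaustive cross-validated model search
#'
#' Evaluates every model of the set by repeated k-fold cross-validation.
#' Within one repeat a single fold partition is shared by all models, so the
#' per-repeat winner (minimal RMSEp; ties broken by fewest included factors,
#' then canonical order) is a fair comparison. Winner tallies and mean RMSEp
#' are accumulated over repeats.
#'
#' @param y outcome vector.
#' @param design result of [build_design_matrix()] (list with `X`, `blocks`).
#' @param models a `model_set` from [enumerate_models()].
#' @param cv a [cv_config()].
#' @return object of class `search_result`: list with `mean_rmse` (per
#'   model), `winners` (per-repeat winning model index), `tally`, `pct`,
#'   `rmse` (models x repeats matrix), `models`, `cv`.
#' @export
run_search_matrix <- function(y, design, models, cv) {
  X <- design$X
  n <- length(y)
  stopifnot(nrow(X) == n)
  folds <- fold_matrix(n, cv)
  M <- length(models)
  cols <- lapply(seq_len(M),
                 function(i) model_columns(models$mask[i, ], design$blocks))
  if (cv$engine == "gram" && cv$orientation == "standard") {
    rmse <- cv_gram_rmse_cpp(X, y, lapply(cols, function(ci) ci - 1L),
                             folds, cv$k)
  } else {
    rmse <- matrix(NA_real_, M, cv$repeats)
    for (r in seq_len(cv$repeats))
      for (i in seq_len(M))
        rmse[i, r] <- cv_rmse(y, X, cols[[i]], folds[, r], cv$orientation)
  }
  n_factors <- rowSums(models$mask)
  winners <- vapply(seq_len(cv$repeats), function(r) {
    v <- rmse[, r]
    # RMSEs within numerical noise of the minimum count as tied (the two
    # engines themselves only agree to ~1e-8); ties go to the most
    # parsimonious model, then canonical order
    cand <- which(v <= min(v) + 1e-7 * (1 + min(v)))
    cand[order(n_factors[cand], cand)][1L]
  }, integer(1))
  tally <- tabulate(winners, nbins = M)
  structure(list(
    mean_rmse = rowMeans(rmse),
    rmse = rmse,
    winners = winners,
    tally = tally,
    pct = 100 * tally / cv$repeats,
    models = models,
    cv = cv
  ), class = "search_result")
}

#' @rdname run_search_matrix
#' @param scored a scored cohort (see [score_cohort()]).
#' @param catalog a [factor_catalog()].
#' @param outcome name of the outcome column (default `mental_health`).
#' @export
run_search <- function(scored, catalog, cv, outcome = "mental_health") {
  design <- build_design_matrix(scored, catalog)
  models <- enumerate_models(catalog)
  out <- run_search_matrix(scored[[outcome]], design, models, cv)
  out$outcome <- outcome
  out
}

#' Top-k table of a search result
#'
#' Models ranked by winner percentage (primary) and mean RMSEp (secondary).
#'
#' @param result a `search_result`.
#' @param k number of rows to return.
#' @return `data.frame` with model index, formula, number of factors, winner
#'   tally, winner percentage, and mean RMSEp.
#' @export
top_models_table <- function(result, k = 3L) {
  M <- length(result$models)
  if (k > M) {
    warning("k exceeds number of models; truncating to ", M)
    k <- M
  }
  ord <- order(-result$pct, result$mean_rmse,
               rowSums(result$models$mask))
  idx <- ord[seq_len(k)]
  data.frame(
    model = idx,
    formula = vapply(idx, function(i)
      mask_formula(result$models$mask[i, ], result$models$factors,
                   result$outcome %||% "y"), character(1)),
    n_factors = rowSums(result$models$mask)[idx],
    wins = result$tally[idx],
    win_pct = result$pct[idx],
    mean_rmsep = result$mean_rmse[idx],
    row.names = NULL
  )
}

#' Extract the winning model of a search as a factor subset
#' @param result a `search_result`.
#' @return character vector of included factor names.
#' @export
best_model <- function(result) {
  idx <- top_models_table(result, 1L)$model
  result$models$factors[result$models$mask[idx, ]]
}

#' Export a search result as per-model and per-repeat tables
#' @param result a `search_result`.
#' @param dir output directory.
#' @return paths of the written CSVs (invisibly).
#' @export
write_search_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_model <- data.frame(
    model = seq_along(result$mean_rmse),
    formula = vapply(seq_len(nrow(result$models$mask)), function(i)
      mask_formula(result$models$mask[i, ], result$models$factors,
                   result$outcome %||% "y"), character(1)),
    wins = result$tally, win_pct = result$pct,
    mean_rmsep = result$mean_rmse)
  p1 <- file.path(dir, "search_per_model.csv")
  write.csv(per_model, p1, row.names = FALSE)
  p2 <- file.path(dir, "search_winners.csv")
  write.csv(data.frame(repeat_ = seq_along(result$winners),
                       winner = result$winners), p2, row.names = FALSE)
  invisible(c(p1, p2))
}
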