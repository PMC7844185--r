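# Inclusion filtering, composite scale scoring, and reliability statistics.

#' Scale definitions of the survey's composite scores
#'
#' Returns the catalog of scale definitions: item columns, aggregation rule
#' and per-item valid range for each composite entering the analysis.
#' Aggregations follow the instruments' scoring rules: the 27 mental-health
#' items are averaged (1-5), resilience (14 items), life stress (7 items) and
#' family conflict (6 items) are summed, father involvement (20 items) is
#' averaged, work stress is a single 1-10 item, and the job-change index
#' counts positives over 13 binary indicators.
#'
#' @return named list of scale definitions (`name`, `item_columns`,
#'   `aggregation`, `valid_range`, `score_range`).
#' @export
scale_catalog <- function() {
  def <- function(name, cols, agg, vr, sr)
    list(name = name, item_columns = cols, aggregation = agg,
         valid_range = vr, score_range = sr)
  list(
    mental_health = def("mental_health", item_cols("mental_health"),
                        "mean", c(1, 5), c(1, 5)),
    resilience = def("resilience", item_cols("resilience"),
                     "sum", c(1, 5), c(14, 70)),
    life_stress = def("life_stress", item_cols("life_stress"),
                      "sum", c(1, 4), c(7, 28)),
    work_stress = def("work_stress", "work_stress",
                      "single_item", c(1, 10), c(1, 10)),
    job_change_index = def("job_change_index",
                           sprintf("job_change_%02d", 1:13),
                           "count_of_positives", c(0, 1), c(0, 13)),
    family_conflict = def("family_conflict", item_cols("family_conflict"),
                          "sum", c(1, 5), c(6, 30)),
    father_involvement = def("father_involvement",
                             item_cols("father_involvement"),
                             "mean", c(1, 5), c(1, 5))
  )
}

#' Apply the study inclusion filter
#'
#' Retains mothers aged 18 or older whose youngest child is between 1 and 10
#' years old; fathers and families with only older (or younger) children are
#' excluded. Counts removed per rule are attached as `attr(, "removed")`.
#'
#' @param table a cohort `data.frame` with `role`, `age` and `age_youngest`
#'   columns.
#' @return the filtered cohort, with removal counts in `attr(, "removed")`.
#' @export
apply_inclusion_filter <- function(table) {
  need <- c("role", "age", "age_youngest")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop_invalid("cohort table lacks required columns: ",
                 paste(miss, collapse = ", "))
  is_mother <- table$role == "mother"
  # age is banded; every band starts at >= 18, so a band label suffices
  adult <- if (is.numeric(table$age)) table$age >= 18 else rep(TRUE, nrow(table))
  child_ok <- table$age_youngest >= 1 & table$age_youngest <= 10
  keep <- is_mother & adult & child_ok
  out <- table[keep, , drop = FALSE]
  attr(out, "removed") <- c(
    fathers = sum(!is_mother),
    underage = sum(is_mother & !adult),
    child_age = sum(is_mother & adult & !child_ok)
  )
  attr(out, "latent") <- NULL
  out
}

#' Score one composite scale
#'
#' Applies the scale's aggregation row-wise. Out-of-range item values raise a
#' validation error naming the first offending row and column; a missing item
#' yields a missing score (no imputation).
#'
#' @param table cohort `data.frame`.
#' @param definition one element of [scale_catalog()].
#' @return numeric vector of scores, `NA` where any item is missing.
#' @export
score_scale <- function(table, definition) {
  cols <- definition$item_columns
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop_invalid("missing item columns: ", paste(miss, collapse = ", "))
  m <- as.matrix(table[, cols, drop = FALSE])
  vr <- definition$valid_range
  bad <- which(!is.na(m) & (m < vr[1] | m > vr[2]), arr.ind = TRUE)
  if (nrow(bad))
    stop_invalid(sprintf(
      "item value out of range [%g, %g] at row %d, column '%s'",
      vr[1], vr[2], bad[1, 1], cols[bad[1, 2]]))
  switch(definition$aggregation,
    mean = rowMeans(m),
    sum = rowSums(m),
    count_of_positives = {
      if (any(!is.na(m) & m != 0 & m != 1))
        stop_invalid("non-binary value in count_of_positives scale '",
                     definition$name, "'")
      rowSums(m)
    },
    single_item = as.numeric(m[, 1]),
    stop_invalid("unknown aggregation: ", definition$aggregation))
}

#' Count of positive indicators among the 13 pandemic job-change items
#' @param indicators numeric/logical vector (or matrix row-wise) of 13 binary
#'   values.
#' @return integer count(s) in 0..13.
#' @export
job_change_index <- function(indicators) {
  x <- if (is.matrix(indicators)) indicators else matrix(indicators, nrow = 1)
  if (ncol(x) != 13L) stop_invalid("expected 13 job-change indicators")
  if (any(!is.na(x) & x != 0 & x != 1))
    stop_invalid("job-change indicators must be binary")
  out <- as.integer(rowSums(x))
  if (!is.matrix(indicators)) out[[1L]] else out
}

#' Score every composite of the catalog onto a cohort
#'
#' @param table cohort `data.frame` (post inclusion filter).
#' @return the table with one derived column per scale appended
#'   (`mental_health`, `resilience`, `life_stress`, `work_stress`,
#'   `job_change_index`, `family_conflict`, `father_involvement`), of class
#'   `scored_cohort`.
#' @export
score_cohort <- function(table) {
  cat_ <- scale_catalog()
  out <- table
  for (sc in names(cat_)) out[[sc]] <- score_scale(table, cat_[[sc]])
  class(out) <- c("scored_cohort", class(out))
  out
}

#' Cronbach's alpha of a multi-item scale
#'
#' \eqn{\alpha = k/(k-1) (1 - \sum_i s_i^2 / s_T^2)} with unbiased (n-1)
#' variance estimates for both the items and the row totals.
#'
#' @param items numeric matrix, respondents in rows, k >= 2 items in columns.
#' @return alpha estimate.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  k <- ncol(m); n <- nrow(m)
  if (k < 2L) stop_invalid("alpha requires at least 2 items")
  if (n < 3L) stop_invalid("alpha requires at least 3 respondents")
  tot_var <- var(rowSums(m))
  if (!is.finite(tot_var) || tot_var <= 0)
    stop_invalid("total score variance is zero; alpha undefined")
  k / (k - 1) * (1 - sum(apply(m, 2, var)) / tot_var)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y equal-length numeric vectors (n >= 3), both nonconstant.
#' @return list with `r` and `p`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_invalid("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop_invalid("correlation undefined for a constant vector")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation matrix of the four mental-health subscale scores
#'
#' The 27 mental-health items group into somatization (6), depression (5),
#' anxiety (6) and post-traumatic stress (10) subscales; this returns the
#' 4x4 Pearson correlation matrix of the subscale mean scores.
#'
#' @param table cohort `data.frame` containing the 27 mental-health items.
#' @return symmetric 4x4 matrix with unit diagonal.
#' @export
subscale_correlation_matrix <- function(table) {
  cols <- item_cols("mental_health")
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop_invalid("missing mental-health items: ", paste(miss, collapse = ", "))
  m <- as.matrix(table[, cols])
  groups <- split(seq_len(27L), rep(seq_along(.mh_subscale_sizes),
                                    .mh_subscale_sizes))
  scores <- vapply(groups, function(i) rowMeans(m[, i, drop = FALSE]),
                   numeric(nrow(m)))
  colnames(scores) <- names(.mh_subscale_sizes)
  for (j in seq_len(ncol(scores)))
    if (sd(scores[, j]) == 0 && nrow(scores) > 1)
      stop_invalid("subscale '", colnames(scores)[j],
                   "' is constant; correlation undefined")
  r <- cor(scores)
  diag(r) <- 1
  r
}
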