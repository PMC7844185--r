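#' @useDynLib maternalcv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm qnorm dnorm integrate uniroot rnorm runif var sd
#'   cor cor.test lm lm.fit coef pchisq pf aov anova chisq.test median
#'   quantile complete.cases setNames density
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed from a global seed and a stream name
#'
#' The generator draws each block of a cohort (demographics, each item scale,
#' outcome noise, ...) from its own named substream so that adding or removing
#' a scale does not perturb the draws of the others. The substream seed is a
#' deterministic 31-bit hash of the global seed and the stream label.
#'
#' @param seed integer global seed.
#' @param name character stream label.
#' @return an integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name),
            length(name) == 1L)
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(name)) {
    h <- (h * 131 + ch) %% m
  }
  # one multiplicative scramble so seed 0 / empty names do not collide trivially
  as.integer((h * 16807) %% m)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

assert_prob_map <- function(p, what) {
  if (abs(sum(p) - 1) > 1e-9)
    stop_invalid(sprintf("prevalences for '%s' must sum to 1 (got %.12f)",
                         what, sum(p)))
  if (any(p < 0)) stop_invalid(sprintf("negative prevalence in '%s'", what))
  invisible(TRUE)
}
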