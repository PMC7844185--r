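#' Compound-symmetric inter-item correlation implied by a target Cronbach's alpha
#'
#' Under compound symmetry (all item pairs share one correlation rho),
#' standardized alpha for k items is \eqn{\alpha = k\rho / (1 + (k-1)\rho)}.
#' This inverts that relation: given the alpha a scale is supposed to attain
#' and its item count, it returns the common inter-item correlation.
#'
#' @param alpha_target target reliability in [0, 1).
#' @param k_items number of items (>= 2).
#' @return the common correlation rho in [0, 1).
#' @examples
#' calibrate_item_correlation(0.96, 27)
#' @export
calibrate_item_correlation <- function(alpha_target, k_items) {
  if (!is.numeric(alpha_target) || length(alpha_target) != 1L ||
      alpha_target < 0 || alpha_target >= 1)
    stop_invalid("alpha_target must be a single value in [0, 1)")
  if (!is.numeric(k_items) || length(k_items) != 1L || k_items < 2)
    stop_invalid("k_items must be an integer >= 2")
  alpha_target / (k_items - alpha_target * (k_items - 1))
}

#' Standardized alpha of k items sharing correlation rho (forward map)
#' @keywords internal
alpha_from_rho <- function(rho, k) k * rho / (1 + (k - 1) * rho)

# Thresholds cutting a standard normal into `levels` equiprobable categories.
ordinal_thresholds <- function(n_levels) {
  qnorm(seq_len(n_levels - 1L) / n_levels)
}

# P(Z1 > a, Z2 > b) for standard bivariate normal with correlation rho,
# by 1-D quadrature of the conditional normal over z1 > a.
bvn_upper <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(pnorm(a, lower.tail = FALSE) *
                                pnorm(b, lower.tail = FALSE))
  s <- sqrt(1 - rho^2)
  f <- function(z) dnorm(z) * pnorm((rho * z - b) / s)
  integrate(f, lower = a, upper = Inf, rel.tol = 1e-10)$value
}

#' Pearson correlation between two discretized standard normals
#'
#' Two latent standard normal variables with correlation `rho_latent` are cut
#' at the same thresholds into ordinal categories 1..L; this returns the exact
#' Pearson correlation of the resulting ordinal pair. Discretization always
#' attenuates: the value is below `rho_latent` in magnitude.
#'
#' @keywords internal
discretized_corr <- function(rho_latent, thresholds) {
  tj <- thresholds
  # ordinal X = 1 + sum_j 1{Z > t_j}; cov(X, Y) expands over indicator pairs
  pj <- pnorm(tj, lower.tail = FALSE)
  cv <- 0
  for (j in seq_along(tj)) for (k in seq_along(tj)) {
    cv <- cv + (bvn_upper(tj[j], tj[k], rho_latent) - pj[j] * pj[k])
  }
  v <- 0
  for (j in seq_along(tj)) for (k in seq_along(tj)) {
    v <- v + (pnorm(max(tj[j], tj[k]), lower.tail = FALSE) - pj[j] * pj[k])
  }
  cv / v
}

# cache for the attenuation inversion (keyed on target and level count)
.rho_cache <- new.env(parent = emptyenv())

#' Latent correlation whose discretized ordinal correlation equals a target
#'
#' Inverse of [discretized_corr()]: finds the correlation two latent normal
#' deviates must share so that, after cutting both into L equiprobable
#' ordinal categories, the observed item correlation hits `rho_observed`.
#'
#' @param rho_observed target correlation on the ordinal scale, in [0, 1).
#' @param n_levels number of ordinal categories (>= 2).
#' @return latent correlation in [rho_observed, 1).
#' @keywords internal
latent_rho_for_observed <- function(rho_observed, n_levels) {
  stopifnot(rho_observed >= 0, rho_observed < 1, n_levels >= 2)
  if (rho_observed == 0) return(0)
  key <- sprintf("%.12f|%d", rho_observed, n_levels)
  hit <- .rho_cache[[key]]
  if (!is.null(hit)) return(hit)
  thr <- ordinal_thresholds(n_levels)
  f <- function(r) discretized_corr(r, thr) - rho_observed
  if (f(0.999999) < 0)
    stop_invalid("target ordinal correlation unattainable under discretization")
  out <- uniroot(f, c(rho_observed * 0.999, 0.999999), tol = 1e-9)$root
  .rho_cache[[key]] <- out
  out
}

#' Within-subscale item correlation calibrated for a multi-subscale composite
#'
#' The 27 mental-health items load on four subscale factors (somatization,
#' depression, anxiety, post-traumatic stress roles) that share one general
#' factor. With within-subscale ordinal item correlation r_w and
#' between-subscale correlation r_w * loading^2, the average inter-item
#' correlation determines standardized alpha of the full composite. This
#' solves for the latent within-subscale correlation such that the composite
#' attains `alpha_target` on the observed ordinal scale.
#'
#' @param alpha_target composite reliability target.
#' @param subscale_sizes integer item counts per subscale.
#' @param loading general-factor loading of each subscale factor, in (0, 1].
#' @param n_levels ordinal levels per item.
#' @return list with latent within (`rho_w`) correlation, the implied observed
#'   within/between item correlations, and the implied observed correlations
#'   between subscale mean scores.
#' @keywords internal
calibrate_subscale_structure <- function(alpha_target, subscale_sizes,
                                         loading, n_levels = 5L) {
  k <- sum(subscale_sizes)
  rbar_target <- calibrate_item_correlation(alpha_target, k)
  n_within <- sum(subscale_sizes * (subscale_sizes - 1) / 2)
  n_total <- k * (k - 1) / 2
  n_between <- n_total - n_within
  thr <- ordinal_thresholds(n_levels)
  lam2 <- loading^2
  f <- function(rw) {
    (n_within * discretized_corr(rw, thr) +
       n_between * discretized_corr(rw * lam2, thr)) / n_total - rbar_target
  }
  rho_w <- uniroot(f, c(1e-6, 0.999999), tol = 1e-9)$root
  r_within_obs <- discretized_corr(rho_w, thr)
  r_between_obs <- discretized_corr(rho_w * lam2, thr)
  # observed correlation between mean scores of subscales a and b
  sub_corr <- function(ka, kb) {
    (ka * kb * r_between_obs) /
      sqrt((ka + ka * (ka - 1) * r_within_obs) *
             (kb + kb * (kb - 1) * r_within_obs))
  }
  m <- length(subscale_sizes)
  sc <- diag(m)
  for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
    sc[a, b] <- sub_corr(subscale_sizes[a], subscale_sizes[b])
  list(rho_w = rho_w, r_within_obs = r_within_obs,
       r_between_obs = r_between_obs, subscale_score_corr = sc)
}
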