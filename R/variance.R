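#' Sampling-point residual variance
#'
#' The two-component residual variance of a sampling point with group sample
#' size `n`: `sigma_w^2 / n + sigma_b^2`. The within-point component shrinks
#' with sample size; the between-point component bounds the precision any
#' single study can attain, however large.
#'
#' @param n Group sample size(s), positive integer.
#' @param sigma_w Within-sampling-point scale (percentage points).
#' @param sigma_b Between-sampling-point scale (percentage points).
#' @return Variance in squared percentage points.
#' @export
sampling_point_variance <- function(n, sigma_w, sigma_b) {
  if (any(!is.finite(n)) || any(n < 1)) {
    stop("n must be >= 1", call. = FALSE)
  }
  if (any(sigma_w <= 0) || any(sigma_b <= 0)) {
    stop("sigma_w and sigma_b must be strictly positive", call. = FALSE)
  }
  sigma_w^2 / n + sigma_b^2
}

#' Regularized-horseshoe local variance
#'
#' The slab-regularized local scale of the regularized horseshoe:
#' `xi_j^2 = c^2 lambda_j^2 / (c^2 + tau^2 lambda_j^2)`. For weakly
#' identified coefficients (small `tau^2 lambda^2` relative to `c^2`) this
#' reverts to the plain horseshoe local variance `lambda^2`; for strongly
#' identified ones it caps the prior scale at `c / tau`, preventing large
#' coefficient values arising from small samples. The value is always
#' strictly below both `lambda^2` and `(c / tau)^2`.
#'
#' @param lambda_j Local scale(s), strictly positive.
#' @param tau Global shrinkage scale, strictly positive.
#' @param c Slab scale, strictly positive.
#' @return `xi^2`, the regularized local variance.
#' @export
regularized_xi_sq <- function(lambda_j, tau, c) {
  if (any(lambda_j <= 0) || any(tau <= 0) || any(c <= 0)) {
    stop("lambda_j, tau and c must be strictly positive", call. = FALSE)
  }
  c^2 * lambda_j^2 / (c^2 + tau^2 * lambda_j^2)
}
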