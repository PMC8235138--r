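## Comparison estimators used in the experiments: the plug-in Gaussian MLE
## density and the (positive-part) James-Stein mean estimator.

#' Plug-in maximum-likelihood Gaussian density
#'
#' @param xbar Sample mean vector.
#' @param Sigma Known covariance (SPD).
#' @return A Gaussian \code{"density_estimate"} \eqn{N(\bar x, \Sigma)}.
#' @export
mle_density_gaussian <- function(xbar, Sigma) {
  de_gaussian(gaussian_model(as.numeric(xbar), Sigma))
}

#' Positive-part James-Stein estimator of a Gaussian mean
#'
#' \eqn{\hat\mu_{JS} = \bar x \cdot \max(0, 1 - (d-2)\sigma^2/(n\|\bar
#' x\|^2))} for \eqn{d \ge 3}; for \eqn{d \le 2} the sample mean is returned
#' unchanged (no shrinkage: the factor's numerator vanishes at d = 2 and the
#' MLE is admissible below d = 3).
#'
#' @param xbar Sample mean vector.
#' @param sigma_sq Known per-coordinate variance.
#' @param n Sample count.
#' @return Shrunken mean vector (the zero vector if \eqn{\|\bar x\| = 0}
#'   with \eqn{d \ge 3}).
#' @export
james_stein <- function(xbar, sigma_sq, n) {
  xbar <- as.numeric(xbar)
  d <- length(xbar)
  if (d <= 2) return(xbar)
  nrm2 <- sum(xbar^2)
  if (nrm2 == 0) return(numeric(d))
  xbar * max(0, 1 - (d - 2) * (sigma_sq / n) / nrm2)
}
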