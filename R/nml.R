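## Normalized maximum likelihood (Shtarkov) estimators over restricted
## classes: the finite-class NML and the closed-form Gaussian-interval NML.

#' Normalized maximum likelihood over a finite discrete class
#'
#' \deqn{q_{nml}(x) = \max_j p_j(x) / Z, \qquad Z = \sum_x \max_j p_j(x),}
#' with worst-case regret \eqn{\Gamma = \log_2 Z} bits attained at every
#' symbol (the constant-regret property). Ties in the maximum need no
#' tie-breaking: only the maximal value enters.
#'
#' @param class A \code{"finite_model_class"} of discrete models.
#' @return Object of class \code{"nml_result"}: \code{estimate} (a discrete
#'   \code{"density_estimate"}), \code{gamma_bits}, \code{z}.
#' @examples
#' cls <- finite_model_class(list(discrete_distribution(c(1, 0)),
#'                                discrete_distribution(c(0, 1))))
#' nml_finite(cls)$gamma_bits  # 1 bit
#' @export
nml_finite <- function(class) {
  stopifnot(inherits(class, "finite_model_class"))
  if (class$type != "discrete") stop("nml_finite requires discrete models")
  mx <- do.call(pmax, lapply(class$models, `[[`, "probs"))
  z <- sum(mx)
  est <- as_density_estimate(discrete_distribution(mx / z))
  structure(list(estimate = est, gamma_bits = log2(z), z = z),
            class = "nml_result")
}

#' @export
print.nml_result <- function(x, ...) {
  cat("NML estimate: Z =", signif(x$z, 8), " Gamma =",
      signif(x$gamma_bits, 8), "bits\n")
  invisible(x)
}

#' Closed-form NML for a symmetric Gaussian-mean interval
#'
#' For the class of unit-scale Gaussians with mean restricted to
#' \eqn{[center - a\sigma, center + a\sigma]} (half-width \code{a} in
#' standardized units), the maximum likelihood over the class at a point is
#' \eqn{\phi(y - clip(y, -a, a))} in standardized coordinates, giving the
#' piecewise density: a Gaussian tail beyond each endpoint and the constant
#' \eqn{\phi(0)} on the interval. The normalizer is closed-form,
#' \eqn{Z = 1 + a\sqrt{2/\pi}}, and \eqn{\Gamma = \log_2 Z}.
#'
#' @param center Interval center (the sample mean).
#' @param a Interval half-width in standardized (sigma = 1) units; > 0
#'   (a = 0 degenerates to the single Gaussian, Gamma = 0).
#' @param sigma Known standard deviation (default 1).
#' @return Object of class \code{"nml_result"} whose estimate has kind
#'   \code{"nml_piecewise"}.
#' @export
nml_gaussian_interval <- function(center, a, sigma = 1) {
  stopifnot(a >= 0, sigma > 0)
  z <- 1 + a * sqrt(2 / pi)
  f <- function(x) {
    y <- (as.numeric(x) - center) / sigma
    stats::dnorm(y - pmin(pmax(y, -a), a), log = TRUE) - log(z) - log(sigma)
  }
  est <- new_density_estimate(f, kind = "nml_piecewise", d = 1L,
                              extra = list(center = center, a = a,
                                           sigma = sigma))
  structure(list(estimate = est, gamma_bits = log2(z), z = z),
            class = "nml_result")
}
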