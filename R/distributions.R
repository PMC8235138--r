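#' Discrete probability distribution over a finite alphabet
#'
#' Constructs a probability vector over the alphabet \code{1, ..., m}. Entries
#' must be nonnegative and sum to one; the stored vector is renormalized so its
#' sum is exactly 1 at machine precision.
#'
#' @param probs Numeric vector of probabilities (length \code{m >= 1}).
#' @return An object of class \code{"discrete_distribution"} with fields
#'   \code{probs} and \code{m} (alphabet size).
#' @examples
#' p <- discrete_distribution(c(0.2, 0.3, 0.5))
#' p$m
#' @export
discrete_distribution <- function(probs) {
  probs <- as.numeric(probs)
  if (length(probs) < 1L) stop("alphabet size must be >= 1")
  if (anyNA(probs)) stop("probabilities must not contain NA")
  if (any(probs < -1e-12)) stop("probabilities must be nonnegative")
  probs[probs < 0] <- 0
  s <- sum(probs)
  if (abs(s - 1) > 1e-8) stop("probabilities must sum to 1 (got ", format(s), ")")
  structure(list(probs = probs / s, m = length(probs)),
            class = "discrete_distribution")
}

#' @export
print.discrete_distribution <- function(x, ...) {
  cat("Discrete distribution over", x$m, "symbols\n")
  show_m <- min(x$m, 10L)
  cat("  p[1:", show_m, "] = ", paste(signif(x$probs[seq_len(show_m)], 4),
                                      collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Multivariate Gaussian model with known covariance
#'
#' @param mean Numeric mean vector (length \code{d}).
#' @param cov \code{d x d} symmetric positive-definite covariance matrix
#'   (a scalar is interpreted as a 1x1 matrix).
#' @return Object of class \code{"gaussian_model"} with fields \code{mean},
#'   \code{cov} and \code{d}.
#' @export
gaussian_model <- function(mean, cov) {
  mean <- as.numeric(mean)
  d <- length(mean)
  cov <- as.matrix(cov)
  if (!all(dim(cov) == d)) stop("cov must be ", d, "x", d)
  if (max(abs(cov - t(cov))) > 1e-10) stop("cov must be symmetric")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("cov must be positive definite")
  structure(list(mean = mean, cov = cov, d = d), class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat("Gaussian model, d =", x$d, "\n  mean:",
      paste(signif(x$mean, 4), collapse = " "), "\n")
  invisible(x)
}

## ---- density estimates -----------------------------------------------------
## A density estimate q(. | x^n) is carried as a log-density evaluator plus a
## kind tag, so that mixtures, NML and discrete estimators share one interface.

new_density_estimate <- function(log_density, kind, d = NULL, m = NULL,
                                 extra = list()) {
  structure(c(list(log_density = log_density, kind = kind, d = d, m = m), extra),
            class = "density_estimate")
}

#' Evaluate the log-density of a density estimate
#'
#' @param q A \code{"density_estimate"}.
#' @param x For continuous estimates, a numeric vector (one point) or a matrix
#'   with one point per row; for discrete estimates, a vector of symbol
#'   indices.
#' @return Numeric vector of log-densities in nats (\code{-Inf} where the
#'   estimate assigns zero mass).
#' @export
eval_log_density <- function(q, x) {
  stopifnot(inherits(q, "density_estimate"))
  q$log_density(x)
}

#' @export
print.density_estimate <- function(x, ...) {
  cat("Density estimate [", x$kind, "]",
      if (!is.null(x$d)) paste0(" d=", x$d) else paste0(" m=", x$m), "\n",
      sep = "")
  invisible(x)
}

#' Density estimate from a discrete distribution
#' @param p A \code{"discrete_distribution"}.
#' @return A \code{"density_estimate"} of kind \code{"discrete"} whose
#'   evaluator maps symbol indices to log-probabilities.
#' @export
as_density_estimate <- function(p) {
  stopifnot(inherits(p, "discrete_distribution"))
  lp <- log(p$probs)
  new_density_estimate(function(x) lp[x], kind = "discrete", m = p$m,
                       extra = list(probs = p$probs))
}

#' Gaussian density estimate
#' @param model A \code{"gaussian_model"}.
#' @return A \code{"density_estimate"} of kind \code{"gaussian"}.
#' @export
de_gaussian <- function(model) {
  stopifnot(inherits(model, "gaussian_model"))
  d <- model$d
  cinv <- solve(model$cov)
  ldet <- determinant(model$cov, logarithm = TRUE)$modulus[1]
  cst <- -0.5 * (d * log(2 * pi) + ldet)
  mu <- model$mean
  f <- function(x) {
    x <- to_points(x, d)
    dx <- sweep(x, 2, mu)
    cst - 0.5 * rowSums((dx %*% cinv) * dx)
  }
  new_density_estimate(f, kind = "gaussian", d = d, extra = list(model = model))
}

#' Gaussian mixture density estimate (shared covariance)
#'
#' @param means Matrix of component means (one per row) or a numeric vector
#'   for d = 1.
#' @param cov Shared covariance matrix.
#' @param weights Mixture weights (nonnegative, summing to 1).
#' @return A \code{"density_estimate"} of kind \code{"gaussian_mixture"}.
#' @export
de_gaussian_mixture <- function(means, cov, weights) {
  if (is.null(dim(means))) means <- matrix(means, ncol = 1)
  d <- ncol(means)
  k <- nrow(means)
  weights <- as.numeric(weights)
  stopifnot(length(weights) == k, all(weights >= 0))
  weights <- weights / sum(weights)
  cov <- as.matrix(cov)
  cinv <- solve(cov)
  ldet <- determinant(cov, logarithm = TRUE)$modulus[1]
  cst <- -0.5 * (d * log(2 * pi) + ldet)
  lw <- ifelse(weights > 0, log(weights), -Inf)
  f <- function(x) {
    x <- to_points(x, d)
    ## n x k matrix of per-component log densities
    ll <- vapply(seq_len(k), function(j) {
      dx <- sweep(x, 2, means[j, ])
      cst - 0.5 * rowSums((dx %*% cinv) * dx) + lw[j]
    }, numeric(nrow(x)))
    if (is.null(dim(ll))) ll <- matrix(ll, nrow = nrow(x))
    apply(ll, 1, logsumexp)
  }
  new_density_estimate(f, kind = "gaussian_mixture", d = d,
                       extra = list(means = means, cov = cov, weights = weights))
}

## internal: coerce a point or set of points to an n x d matrix
to_points <- function(x, d) {
  if (is.null(dim(x))) {
    if (d == 1L) matrix(x, ncol = 1) else matrix(x, ncol = d, byrow = TRUE)
  } else as.matrix(x)
}

logsumexp <- function(v) {
  mx <- max(v)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(v - mx)))
}
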