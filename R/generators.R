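## Seeded synthetic-data generators for the distribution families the
## experiments use: Zipf, truncated geometric, uniform and Gaussian.

#' Zipf's law probability mass function
#'
#' \eqn{p(i) \propto i^{-s}} over the alphabet \eqn{1, ..., m}; the benchmark
#' family for natural count data.
#'
#' @param m Alphabet size.
#' @param s Exponent (>= 0; s = 0 gives the uniform distribution).
#' @return A \code{"discrete_distribution"}.
#' @examples
#' zipf_pmf(2, 1)$probs  # 2/3, 1/3
#' @export
zipf_pmf <- function(m, s) {
  stopifnot(m >= 1, s >= 0)
  w <- seq_len(m)^(-s)
  discrete_distribution(w / sum(w))
}

#' Truncated geometric probability mass function
#'
#' \eqn{p(i) \propto (1-s)^{i-1} s}, truncated at \eqn{m} and renormalized
#' (for small \code{s} and large \code{m} the discarded tail mass is
#' negligible).
#'
#' @param m Alphabet size.
#' @param s Success probability in (0, 1].
#' @return A \code{"discrete_distribution"}.
#' @export
geometric_pmf <- function(m, s) {
  stopifnot(m >= 1, s > 0, s <= 1)
  if (s == 1) return(discrete_distribution(c(1, numeric(m - 1L))))
  lw <- (seq_len(m) - 1) * log1p(-s) + log(s)
  w <- exp(lw - max(lw))
  discrete_distribution(w / sum(w))
}

#' Generator specification
#'
#' @param family One of \code{"zipf"}, \code{"geometric"}, \code{"uniform"},
#'   \code{"gaussian"}.
#' @param m Alphabet size (discrete families).
#' @param s Family parameter (Zipf exponent / geometric success prob).
#' @param mean,cov Gaussian mean vector and covariance.
#' @param seed Default seed used by \code{\link{sample_generator}}.
#' @return Object of class \code{"generator_spec"}; field \code{pmf} holds
#'   the discrete truth (discrete families), field \code{model} the Gaussian
#'   truth.
#' @export
generator_spec <- function(family = c("zipf", "geometric", "uniform",
                                      "gaussian"),
                           m = NULL, s = NULL, mean = NULL, cov = NULL,
                           seed = 1L) {
  family <- match.arg(family)
  out <- list(family = family, seed = as.integer(seed))
  if (family == "gaussian") {
    out$model <- gaussian_model(mean, if (is.null(cov)) diag(length(mean))
                                      else cov)
  } else {
    stopifnot(!is.null(m))
    out$m <- as.integer(m)
    out$s <- s
    out$pmf <- switch(family,
                      zipf = zipf_pmf(m, s),
                      geometric = geometric_pmf(m, s),
                      uniform = discrete_distribution(rep(1 / m, m)))
  }
  structure(out, class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("Generator:", x$family,
      if (x$family == "gaussian") paste0("d=", x$model$d)
      else paste0("m=", x$m, if (!is.null(x$s)) paste0(", s=", x$s)),
      " seed=", x$seed, "\n")
  invisible(x)
}

#' Draw i.i.d. samples from a generator
#'
#' Identical \code{(spec, n, seed)} always produces identical output. For
#' discrete families the result is a \code{"count_vector"} (the sufficient
#' statistic); for the Gaussian family an \code{n x d} sample matrix.
#'
#' @param spec A \code{"generator_spec"}.
#' @param n Number of draws (>= 0).
#' @param seed Seed for this draw; defaults to the spec's seed. \code{NULL}
#'   continues the current RNG stream (used by the harness, which manages
#'   replicate seeds itself).
#' @return A \code{"count_vector"} or numeric matrix.
#' @export
sample_generator <- function(spec, n, seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (spec$family == "gaussian") {
    d <- spec$model$d
    L <- t(chol(spec$model$cov))
    z <- matrix(stats::rnorm(n * d), ncol = d)
    sweep(z %*% t(L), 2, spec$model$mean, "+")
  } else {
    p <- spec$pmf$probs
    if (n == 0) return(count_vector(integer(spec$m)))
    count_vector(drop(stats::rmultinom(1, n, p)))
  }
}
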