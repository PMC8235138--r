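## Kullback-Leibler divergence and log-loss, the loss measures used by every
## estimator in the package. Internal computation is in nats; reporting
## defaults to bits.

LOG2 <- log(2)

to_unit <- function(x_nats, unit) {
  unit <- resolve_unit(unit)
  if (unit == "bits") x_nats / LOG2 else x_nats
}

resolve_unit <- function(unit) {
  if (is.numeric(unit)) {
    if (isTRUE(all.equal(unit, 2))) return("bits")
    if (isTRUE(all.equal(unit, exp(1)))) return("nats")
    stop("log base must be 2 or e")
  }
  match.arg(unit, c("bits", "nats"))
}

#' Kullback-Leibler divergence between discrete distributions
#'
#' Computes \eqn{D(p\|q) = \sum_i p_i \log(p_i/q_i)}. Terms with
#' \eqn{p_i = 0} contribute zero; if some \eqn{p_i > 0} where \eqn{q_i = 0}
#' the divergence is \code{Inf} (an unbounded-divergence event, as for the
#' plug-in MLE with unseen symbols).
#'
#' @param p,q \code{"discrete_distribution"} objects on the same alphabet.
#' @param unit \code{"bits"} (default) or \code{"nats"}; the numeric bases
#'   \code{2} and \code{exp(1)} are also accepted.
#' @return Nonnegative scalar divergence, possibly \code{Inf}.
#' @examples
#' p <- discrete_distribution(c(1, 0))
#' q <- discrete_distribution(c(0.5, 0.5))
#' kl_discrete(p, q)  # 1 bit
#' @export
kl_discrete <- function(p, q, unit = "bits") {
  stopifnot(inherits(p, "discrete_distribution"),
            inherits(q, "discrete_distribution"))
  if (p$m != q$m) stop("alphabet sizes differ: ", p$m, " vs ", q$m)
  kl <- kl_vec(p$probs, q$probs)
  to_unit(kl, unit)
}

## internal: KL in nats between raw probability vectors
kl_vec <- function(pv, qv) {
  act <- pv > 0
  if (any(qv[act] == 0)) return(Inf)
  sum(pv[act] * (log(pv[act]) - log(qv[act])))
}

#' Quadrature scheme for continuous KL integrals
#'
#' For dimension \code{d <= 2} a tensor Gauss-Hermite rule under the true
#' Gaussian is used (deterministic); for \code{d > 2} seeded Monte-Carlo
#' sampling from the true Gaussian.
#'
#' @param gh_nodes Gauss-Hermite nodes per axis (default 200).
#' @param mc_samples Monte-Carlo sample count for d > 2 (default 200000).
#' @param mc_seed Seed for the Monte-Carlo branch.
#' @return Object of class \code{"quadrature_spec"}.
#' @export
quadrature_spec <- function(gh_nodes = 200L, mc_samples = 200000L,
                            mc_seed = 1L) {
  structure(list(gh_nodes = as.integer(gh_nodes),
                 mc_samples = as.integer(mc_samples),
                 mc_seed = as.integer(mc_seed)),
            class = "quadrature_spec")
}

## Gauss-Hermite nodes/weights (physicists' convention), cached per node count
.gh_cache <- new.env(parent = emptyenv())
gh_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

#' KL divergence from a Gaussian to an arbitrary density estimate
#'
#' Approximates \eqn{\int p_\theta(x) \log(p_\theta(x)/q(x)) dx} where
#' \eqn{p_\theta} is Gaussian. The entropy term is exact; the cross-entropy is
#' integrated by tensor Gauss-Hermite quadrature (d of 1 or 2) or seeded
#' Monte-Carlo (d > 2). A result within \code{1e-9} of zero is clamped to 0.
#'
#' @param p A \code{"gaussian_model"} (the true distribution).
#' @param q A \code{"density_estimate"}.
#' @param scheme A \code{"quadrature_spec"}.
#' @param unit Reporting unit, \code{"bits"} or \code{"nats"} (default bits).
#' @return Nonnegative divergence; \code{Inf} if \code{q} vanishes on a
#'   quadrature node with positive weight.
#' @export
kl_gaussian_vs_density <- function(p, q, scheme = quadrature_spec(),
                                   unit = "bits") {
  stopifnot(inherits(p, "gaussian_model"), inherits(q, "density_estimate"))
  d <- p$d
  ldet <- determinant(p$cov, logarithm = TRUE)$modulus[1]
  neg_entropy <- -0.5 * (d * log(2 * pi * exp(1)) + ldet)  # E_p log p
  L <- t(chol(p$cov))                                      # lower factor
  if (d <= 2L) {
    rule <- gh_rule(scheme$gh_nodes)
    if (d == 1L) {
      pts <- matrix(rule$x, ncol = 1)
      w <- rule$w
    } else {
      g <- expand.grid(i = seq_along(rule$x), j = seq_along(rule$x))
      pts <- cbind(rule$x[g$i], rule$x[g$j])
      w <- rule$w[g$i] * rule$w[g$j]
    }
    ## x = mu + sqrt(2) L z ;  int N(x) f(x) dx = pi^{-d/2} sum w f(x_i)
    x <- sweep(pts %*% (sqrt(2) * t(L)), 2, p$mean, "+")
    lq <- q$log_density(x)
    if (any(!is.finite(lq) & w > 0)) return(Inf)
    cross <- sum(w * lq) / pi^(d / 2)
  } else {
    set.seed(scheme$mc_seed)
    z <- matrix(stats::rnorm(scheme$mc_samples * d), ncol = d)
    x <- sweep(z %*% t(L), 2, p$mean, "+")
    lq <- q$log_density(x)
    if (any(!is.finite(lq))) return(Inf)
    cross <- mean(lq)
  }
  val <- neg_entropy - cross
  if (abs(val) < 1e-9) val <- 0
  to_unit(val, unit)
}

#' Log-loss regret of one estimate against another at a point
#'
#' Returns \eqn{-\log q(x) + \log p(x)}, the excess logarithmic loss of
#' \code{q} over \code{p} at \code{x}. Its expectation under \code{p} is the
#' KL divergence \eqn{D(p\|q)}.
#'
#' @param x Evaluation point (symbol index or numeric vector).
#' @param q,p \code{"density_estimate"} objects evaluable at \code{x}.
#' @param unit Reporting unit (default bits).
#' @return Scalar regret (can be negative at individual points).
#' @export
logloss_regret <- function(x, q, p, unit = "bits") {
  lq <- eval_log_density(q, x)
  lp <- eval_log_density(p, x)
  to_unit(lp - lq, unit)
}
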