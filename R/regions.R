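## Data-driven restricted model classes: Gaussian-mean confidence ellipsoids
## (with whitening) and Sison-Glaz box-simplex regions for multinomial
## proportions, with vertex enumeration of the box-simplex intersection.

#' Confidence ellipsoid for a Gaussian mean
#'
#' The 100(1-alpha)% confidence region for the mean of \eqn{N(\mu, \Sigma)}
#' from \code{n} i.i.d. samples with known covariance:
#' \deqn{\{\mu : (\bar x - \mu)^T \Sigma^{-1} (\bar x - \mu) \le
#'       \chi^2_d(1-\alpha)/n\}.}
#'
#' @param xbar Sample mean vector.
#' @param Sigma Known covariance matrix (SPD).
#' @param n Sample count (>= 1).
#' @param alpha Miscoverage level in (0, 1).
#' @return Object of class \code{"ellipsoid_region"} with fields
#'   \code{center}, \code{shape}, \code{radius_sq}, \code{alpha}, \code{n},
#'   \code{d}.
#' @examples
#' r <- gaussian_mean_region(0, 1, n = 25, alpha = 0.05)
#' sqrt(r$radius_sq)  # half-width 1.96/5
#' @export
gaussian_mean_region <- function(xbar, Sigma, n, alpha) {
  xbar <- as.numeric(xbar)
  d <- length(xbar)
  Sigma <- as.matrix(Sigma)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  if (n < 1) stop("n must be >= 1")
  gm <- gaussian_model(xbar, Sigma)  # validates SPD/symmetry
  structure(list(center = xbar, shape = gm$cov,
                 radius_sq = stats::qchisq(1 - alpha, df = d) / n,
                 alpha = alpha, n = as.integer(n), d = d),
            class = "ellipsoid_region")
}

#' @export
print.ellipsoid_region <- function(x, ...) {
  cat("Gaussian-mean confidence ellipsoid: d =", x$d,
      " alpha =", x$alpha, " n =", x$n, "\n  radius^2 =",
      signif(x$radius_sq, 6), "\n")
  invisible(x)
}

#' Membership test for an ellipsoid region
#' @param region An \code{"ellipsoid_region"}.
#' @param mu Candidate mean vector.
#' @param tol Slack on the quadratic form boundary.
#' @return Logical.
#' @export
in_region <- function(region, mu, tol = 1e-10) {
  dx <- as.numeric(mu) - region$center
  drop(t(dx) %*% solve(region$shape, dx)) <= region$radius_sq + tol
}

#' Whiten an ellipsoid region to the unit-shape case
#'
#' Returns the affine map \eqn{T(\mu) = \Sigma^{-1/2}(\mu - \bar x)} under
#' which the region becomes the centered ball
#' \eqn{\{\mu' : \|\mu'\|^2 \le radius\_sq\}}. KL divergences between
#' equal-covariance Gaussians are invariant under this map, so minimax
#' solutions can be computed in whitened coordinates and mapped back.
#'
#' @param region An \code{"ellipsoid_region"}.
#' @return List with \code{transform} and \code{inverse} (vector or row-matrix
#'   maps), the matrices \code{sqrt_inv} (\eqn{\Sigma^{-1/2}}) and \code{sqrt}
#'   (\eqn{\Sigma^{1/2}}), and \code{region}, the whitened
#'   \code{"ellipsoid_region"} with identity shape.
#' @export
whiten <- function(region) {
  stopifnot(inherits(region, "ellipsoid_region"))
  e <- eigen(region$shape, symmetric = TRUE)
  s_inv <- e$vectors %*% diag(1 / sqrt(e$values), region$d) %*% t(e$vectors)
  s_half <- e$vectors %*% diag(sqrt(e$values), region$d) %*% t(e$vectors)
  center <- region$center
  wr <- region
  wr$center <- rep(0, region$d)
  wr$shape <- diag(region$d)
  list(
    transform = function(mu) {
      mu <- to_points(mu, region$d)
      sweep(mu, 2, center) %*% t(s_inv)
    },
    inverse = function(mu) {
      mu <- to_points(mu, region$d)
      sweep(mu %*% t(s_half), 2, center, "+")
    },
    sqrt_inv = s_inv, sqrt = s_half, region = wr)
}

## ---- Sison-Glaz simultaneous intervals -------------------------------------

## moments of a Poisson(lambda) truncated to [a, b] (direct summation)
trunc_pois_moments <- function(lambda, a, b) {
  a <- max(a, 0L)
  k <- a:b
  pk <- stats::dpois(k, lambda)
  prob <- sum(pk)
  if (prob <= 0) return(list(prob = 0, mean = lambda, var = 0, mu3 = 0, mu4 = 0))
  w <- pk / prob
  mu <- sum(k * w)
  ck <- k - mu
  list(prob = prob, mean = mu, var = sum(ck^2 * w),
       mu3 = sum(ck^3 * w), mu4 = sum(ck^4 * w))
}

## Edgeworth-corrected coverage approximation for half-width c (in counts)
sg_coverage <- function(counts, n, c) {
  mom <- lapply(counts, function(k) trunc_pois_moments(k, k - c, k + c))
  probs <- vapply(mom, `[[`, numeric(1), "prob")
  if (any(probs <= 0)) return(0)
  mu_s <- sum(vapply(mom, `[[`, numeric(1), "mean"))
  var_s <- sum(vapply(mom, `[[`, numeric(1), "var"))
  if (var_s <= 0) return(if (abs(mu_s - n) < 1e-9) 1 else 0)
  mu3_s <- sum(vapply(mom, `[[`, numeric(1), "mu3"))
  mu4_s <- sum(vapply(mom, function(m) m$mu4 - 3 * m$var^2, numeric(1)))
  sg <- sqrt(var_s)
  z <- (n - mu_s) / sg
  g1 <- mu3_s / sg^3
  g2 <- mu4_s / sg^4
  fe <- stats::dnorm(z) * (1 + g1 * (z^3 - 3 * z) / 6 +
                             g2 * (z^4 - 6 * z^2 + 3) / 24 +
                             g1^2 * (z^6 - 15 * z^4 + 45 * z^2 - 15) / 72) / sg
  prod(probs) * fe / stats::dpois(n, n)
}

#' Sison-Glaz simultaneous confidence intervals for multinomial proportions
#'
#' Builds the rectangular simultaneous region
#' \eqn{\{p : p_l(i) \le p(i) \le p_u(i)\}} by the truncated-Poisson /
#' Edgeworth construction: the common integer half-width \eqn{\tau} is the one
#' whose approximate coverage brackets \eqn{1-\alpha}, with a fractional
#' correction \eqn{2\gamma/n} added to the upper limits.
#'
#' @param counts Nonnegative integer cell counts (or a \code{"count_vector"}).
#' @param alpha Miscoverage level in (0, 1).
#' @return Object of class \code{"box_simplex_region"} with fields
#'   \code{lower}, \code{upper}, \code{alpha} (bounds clipped to [0, 1] and,
#'   in degenerate small-n cases, relaxed to the nearest box intersecting the
#'   simplex).
#' @references Sison, C.P. and Glaz, J. (1995) Simultaneous confidence
#'   intervals and sample size determination for multinomial proportions.
#'   JASA 90, 366-369.
#' @export
sison_glaz_intervals <- function(counts, alpha) {
  if (inherits(counts, "count_vector")) counts <- counts$counts
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("Sison-Glaz region undefined for n = 0")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  phat <- counts / n
  ## find integer tau with nu(tau) < 1-alpha <= nu(tau+1)
  nu_prev <- sg_coverage(counts, n, 0)
  tau <- NA_integer_
  gamma <- 0
  for (c in 0:n) {
    nu_next <- sg_coverage(counts, n, c + 1)
    if (nu_prev < 1 - alpha && nu_next >= 1 - alpha) {
      tau <- c
      gamma <- (1 - alpha - nu_prev) / (nu_next - nu_prev)
      break
    }
    nu_prev <- nu_next
  }
  if (is.na(tau)) {  # coverage already above 1-alpha at c = 0 (tiny n)
    tau <- 0
    gamma <- 0
  }
  lower <- pmax(phat - tau / n, 0)
  upper <- pmin(phat + tau / n + 2 * gamma / n, 1)
  bounds <- relax_to_feasible(lower, upper)
  structure(list(lower = bounds$lower, upper = bounds$upper, alpha = alpha,
                 n = n, tau = tau, gamma = gamma),
            class = "box_simplex_region")
}

## if the clipped box misses the simplex (pathological tiny-n cases), move the
## offending bounds uniformly to the nearest feasible box
relax_to_feasible <- function(lower, upper) {
  m <- length(lower)
  while (sum(lower) > 1 + 1e-12) {
    pos <- lower > 0
    lower[pos] <- pmax(lower[pos] - (sum(lower) - 1) / sum(pos), 0)
  }
  while (sum(upper) < 1 - 1e-12) {
    room <- upper < 1
    upper[room] <- pmin(upper[room] + (1 - sum(upper)) / sum(room), 1)
  }
  list(lower = lower, upper = upper)
}

#' Construct a box-simplex region directly from bounds
#' @param lower,upper Per-category probability bounds.
#' @param alpha Nominal miscoverage (informational).
#' @return Object of class \code{"box_simplex_region"}.
#' @export
box_simplex_region <- function(lower, upper, alpha = NA_real_) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper))
  if (any(lower < -1e-12) || any(upper > 1 + 1e-12) || any(lower > upper + 1e-12))
    stop("need 0 <= lower <= upper <= 1 per category")
  if (sum(lower) > 1 + 1e-9 || sum(upper) < 1 - 1e-9)
    stop("box does not intersect the probability simplex")
  structure(list(lower = pmin(pmax(lower, 0), 1),
                 upper = pmin(pmax(upper, 0), 1), alpha = alpha),
            class = "box_simplex_region")
}

#' @export
print.box_simplex_region <- function(x, ...) {
  cat("Box-simplex region, m =", length(x$lower),
      if (!is.na(x$alpha)) paste(" alpha =", x$alpha), "\n")
  for (i in seq_along(x$lower)) {
    cat(sprintf("  p(%d) in [%.4f, %.4f]\n", i, x$lower[i], x$upper[i]))
  }
  invisible(x)
}

#' Finite class of candidate models
#'
#' An indexed list of models (all \code{"discrete_distribution"} on one
#' alphabet, or all \code{"gaussian_model"} of one dimension) used as the
#' support of capacity / NML computations.
#'
#' @param models List of models.
#' @param labels Optional per-model identifiers.
#' @return Object of class \code{"finite_model_class"} with fields
#'   \code{models}, \code{labels}, \code{type} and \code{m} or \code{d}.
#' @export
finite_model_class <- function(models, labels = NULL) {
  if (length(models) < 1) stop("model class must be nonempty")
  if (inherits(models[[1]], "discrete_distribution")) {
    type <- "discrete"
    m <- models[[1]]$m
    ok <- vapply(models, function(p) inherits(p, "discrete_distribution") &&
                   p$m == m, logical(1))
    if (!all(ok)) stop("all models must be discrete on one alphabet")
    out <- list(models = models, type = type, m = m)
  } else if (inherits(models[[1]], "gaussian_model")) {
    d <- models[[1]]$d
    ok <- vapply(models, function(p) inherits(p, "gaussian_model") &&
                   p$d == d, logical(1))
    if (!all(ok)) stop("all models must be Gaussian of one dimension")
    out <- list(models = models, type = "gaussian", d = d)
  } else stop("unsupported model type")
  out$labels <- if (is.null(labels)) as.character(seq_along(models)) else labels
  structure(out, class = "finite_model_class")
}

#' @export
print.finite_model_class <- function(x, ...) {
  cat("Finite model class:", length(x$models), x$type, "models",
      if (x$type == "discrete") paste("on", x$m, "symbols")
      else paste("in dimension", x$d), "\n")
  invisible(x)
}

#' Enumerate the vertices of a box-simplex region
#'
#' Vertices of \eqn{\{p : l \le p \le u, \sum_i p_i = 1\}}. At a vertex at
#' most one coordinate is strictly between its bounds, so enumeration fixes
#' every coordinate but one at a bound, solves for the free coordinate and
#' keeps feasible solutions (deduplicated within 1e-10). Exhaustive over the
#' \eqn{2^{m-1}} bound assignments; limited to \code{m <= 12}.
#'
#' @param region A \code{"box_simplex_region"}.
#' @return A \code{"finite_model_class"} of the vertex distributions.
#' @export
enumerate_vertices <- function(region) {
  stopifnot(inherits(region, "box_simplex_region"))
  l <- region$lower; u <- region$upper
  m <- length(l)
  if (m > 12) stop("vertex enumeration supported for m <= 12")
  if (sum(l) > 1 + 1e-12 || sum(u) < 1 - 1e-12) stop("empty box-simplex region")
  verts <- list()
  if (m == 1L) {
    verts[[1]] <- 1
  } else {
    combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m - 1)))
    for (free in seq_len(m)) {
      others <- setdiff(seq_len(m), free)
      base_l <- l[others]; base_u <- u[others]
      for (r in seq_len(nrow(combos))) {
        vals <- ifelse(combos[r, ], base_u, base_l)
        pf <- 1 - sum(vals)
        if (pf >= l[free] - 1e-12 && pf <= u[free] + 1e-12) {
          v <- numeric(m)
          v[others] <- vals
          v[free] <- pf
          verts[[length(verts) + 1L]] <- v
        }
      }
    }
  }
  if (length(verts) == 0) stop("empty box-simplex region")
  vm <- unique(round(do.call(rbind, verts), 10))
  models <- lapply(seq_len(nrow(vm)), function(i) {
    p <- pmin(pmax(vm[i, ], 0), 1)
    discrete_distribution(p / sum(p))
  })
  finite_model_class(models, labels = paste0("v", seq_along(models)))
}
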