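## Redundancy-capacity solvers. The minimax estimator over a restricted model
## class is the capacity-achieving mixture of the channel whose transition
## rows are the class members; the robust (projected-mixture) variant solves
## the constrained capacity problem by alternating the two fixed-point
## updates of its variational form.

## ---- channel discretization ------------------------------------------------

#' Evaluation grid for continuous model classes
#'
#' A quadrature support for Blahut-Arimoto over Gaussian classes: points with
#' weights such that row likelihoods integrate to ~1.
#'
#' @param points Matrix of support points (one per row) or vector for d = 1.
#' @param weights Quadrature weights (positive, one per point).
#' @return Object of class \code{"eval_grid"}.
#' @export
eval_grid <- function(points, weights) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  stopifnot(nrow(points) == length(weights), all(weights > 0))
  structure(list(points = points, weights = as.numeric(weights)),
            class = "eval_grid")
}

## uniform tensor grid covering [-extent, extent]^d (whitened coordinates)
uniform_tensor_grid <- function(d, extent, n_per_axis) {
  x1 <- seq(-extent, extent, length.out = n_per_axis)
  h <- x1[2] - x1[1]
  if (d == 1L) {
    eval_grid(matrix(x1, ncol = 1), rep(h, n_per_axis))
  } else {
    g <- as.matrix(expand.grid(x1, x1))
    eval_grid(g, rep(h^2, nrow(g)))
  }
}

## likelihood matrix: rows = models evaluated on the support, weighted so each
## row sums to (approximately) one
channel_matrix <- function(class, support = NULL) {
  if (class$type == "discrete") {
    P <- do.call(rbind, lapply(class$models, function(p) p$probs))
    list(P = P, support = NULL)
  } else {
    if (is.null(support)) stop("a quadrature support is required for Gaussian classes")
    stopifnot(inherits(support, "eval_grid"))
    P <- do.call(rbind, lapply(class$models, function(gm) {
      de <- de_gaussian(gm)
      exp(de$log_density(support$points)) * support$weights
    }))
    P <- P / rowSums(P)  # absorb truncation error of the finite grid
    list(P = P, support = support)
  }
}

## per-model divergences (nats) to a mixture column vector q on the support;
## rowneg = rowSums(P * log P) precomputed. Columns where q = 0 but some row
## has mass yield Inf rows, as they must.
row_divergences <- function(P, rowneg, logq) {
  zero_q <- !is.finite(logq)
  if (any(zero_q)) {
    hit <- rowSums(P[, zero_q, drop = FALSE]) > 0
    logq[zero_q] <- 0
    D <- rowneg - drop(P %*% logq)
    D[hit] <- Inf
    D
  } else {
    rowneg - drop(P %*% logq)
  }
}

## ---- Blahut-Arimoto --------------------------------------------------------

#' Channel capacity over a finite model class (Blahut-Arimoto)
#'
#' Solves \eqn{\sup_\pi I(T;X)} for the channel whose transition rows are the
#' class members; by the redundancy-capacity equivalence the maximizing prior
#' yields the minimax mixture estimator and the capacity equals the minimal
#' worst-case KL divergence over the class. Initialization is the uniform
#' prior; the per-iteration capacity lower bound is nondecreasing, and
#' convergence is declared when the capacity gap
#' \eqn{\max_j D(p_j\|q_\pi) - \sum_j \pi_j D(p_j\|q_\pi)} drops below
#' \code{tol}.
#'
#' @param class A \code{"finite_model_class"}.
#' @param support For Gaussian classes, an \code{"eval_grid"}; ignored for
#'   discrete classes.
#' @param tol Capacity-gap tolerance in bits (default 1e-9).
#' @param max_iter Iteration cap (default 10000).
#' @return Object of class \code{"capacity_result"}: \code{capacity_bits},
#'   \code{prior}, \code{mixture} (a \code{"density_estimate"}),
#'   \code{per_model_divergence} (bits), \code{iterations}, \code{converged}.
#' @examples
#' cls <- finite_model_class(list(discrete_distribution(c(1, 0)),
#'                                discrete_distribution(c(0, 1))))
#' blahut_arimoto(cls)$capacity_bits  # 1 bit: noiseless binary channel
#' @export
blahut_arimoto <- function(class, support = NULL, tol = 1e-9,
                           max_iter = 10000L) {
  stopifnot(inherits(class, "finite_model_class"))
  ch <- channel_matrix(class, support)
  ba <- ba_core(ch$P, tol = tol, max_iter = max_iter)
  mixture <- mixture_estimate(class, ba$prior)
  structure(list(capacity_bits = ba$capacity / LOG2,
                 prior = ba$prior,
                 mixture = mixture,
                 per_model_divergence = ba$D / LOG2,
                 iterations = ba$iterations,
                 converged = ba$converged,
                 monotone = ba$monotone,
                 class = class),
            class = "capacity_result")
}

## plain BA on a likelihood matrix; exponent_offset (nats, per row) turns the
## same fixed point into the constrained-capacity update (see
## constrained_capacity): offset 0 recovers standard BA.
ba_core <- function(P, tol, max_iter, exponent_offset = NULL) {
  J <- nrow(P)
  logP <- log(P)
  logP[P == 0] <- 0
  rowneg <- rowSums(P * logP)  # sum_x p log p per model
  off <- if (is.null(exponent_offset)) numeric(J) else exponent_offset
  lpi <- rep(-log(J), J)
  tol_nats <- tol * LOG2
  converged <- FALSE
  monotone <- TRUE
  prev_lower <- -Inf
  it <- 0L
  obj <- D <- NULL
  repeat {
    it <- it + 1L
    pi_w <- exp(lpi - max(lpi))
    pi_w <- pi_w / sum(pi_w)
    q <- drop(crossprod(P, pi_w))
    logq <- ifelse(q > 0, log(q), -Inf)
    D <- row_divergences(P, rowneg, logq)
    score <- D - off
    lower <- sum(pi_w * score)
    upper <- max(score)
    if (lower < prev_lower - 1e-12) monotone <- FALSE
    prev_lower <- lower
    obj <- lower
    if (upper - lower < tol_nats) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    lpi <- lpi + score
    lpi <- lpi - max(lpi)
  }
  pi_w <- exp(lpi - max(lpi))
  pi_w <- pi_w / sum(pi_w)
  list(capacity = obj, prior = pi_w, D = D, iterations = it,
       converged = converged, monotone = monotone,
       q = drop(crossprod(P, pi_w)))
}

## mixture of class members under a prior, as a density estimate
mixture_estimate <- function(class, prior) {
  if (class$type == "discrete") {
    probs <- Reduce(`+`, Map(function(p, w) w * p$probs, class$models,
                             as.list(prior)))
    as_density_estimate(discrete_distribution(probs / sum(probs)))
  } else {
    keep <- prior > 1e-12
    means <- do.call(rbind, lapply(class$models[keep], `[[`, "mean"))
    de_gaussian_mixture(means, class$models[[1]]$cov, prior[keep])
  }
}

#' @export
print.capacity_result <- function(x, ...) {
  cat("Capacity result: C =", signif(x$capacity_bits, 8), "bits,",
      x$iterations, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  prior support:", sum(x$prior > 1e-6), "of", length(x$prior),
      "models\n")
  invisible(x)
}

## ---- region discretization + minimax ---------------------------------------

#' Discretization settings for continuous regions
#'
#' @param n_boundary Boundary points for d = 2 ellipsoids (default 360
#'   equally spaced angles).
#' @param n_interior Interior grid points per axis added to the boundary
#'   support (d = 1; default 0, endpoints only).
#' @param grid_points Quadrature points per axis for the evaluation support.
#' @param grid_extent Half-width of the evaluation support in whitened
#'   coordinates beyond which density mass is negligible.
#' @return Object of class \code{"discretization_spec"}.
#' @export
discretization_spec <- function(n_boundary = 360L, n_interior = 0L,
                                grid_points = NULL, grid_extent = NULL) {
  structure(list(n_boundary = as.integer(n_boundary),
                 n_interior = as.integer(n_interior),
                 grid_points = grid_points, grid_extent = grid_extent),
            class = "discretization_spec")
}

#' Data-driven minimax mixture estimator over a confidence region
#'
#' Discretizes the region (ellipsoid boundary support for the Gaussian case;
#' the vertex set of the box-simplex polytope for the multinomial case) and
#' runs \code{\link{blahut_arimoto}}; the returned mixture is the minimax
#' density estimator for the region and the capacity is the minimal
#' worst-case divergence.
#'
#' @param region An \code{"ellipsoid_region"} or \code{"box_simplex_region"}.
#' @param resolution A \code{"discretization_spec"}.
#' @param tol,max_iter Passed to \code{\link{blahut_arimoto}}.
#' @return A \code{"capacity_result"}; for ellipsoid regions the mixture is a
#'   Gaussian mixture in the original (unwhitened) coordinates.
#' @export
mixture_minimax <- function(region, resolution = discretization_spec(),
                            tol = 1e-9, max_iter = 10000L) {
  if (inherits(region, "box_simplex_region")) {
    cls <- enumerate_vertices(region)
    return(blahut_arimoto(cls, tol = tol, max_iter = max_iter))
  }
  stopifnot(inherits(region, "ellipsoid_region"))
  d <- region$d
  if (d > 2) stop("mixture_minimax supports ellipsoids of dimension <= 2")
  w <- whiten(region)
  a <- sqrt(region$radius_sq)
  if (d == 1L) {
    mus <- c(-a, a)
    if (resolution$n_interior > 0) {
      mus <- sort(unique(c(mus, seq(-a, a, length.out = resolution$n_interior + 2L))))
    }
    mus_w <- matrix(mus, ncol = 1)
  } else {
    ang <- seq(0, 2 * pi, length.out = resolution$n_boundary + 1L)[-1L]
    mus_w <- a * cbind(cos(ang), sin(ang))
  }
  n_ax <- resolution$grid_points
  if (is.null(n_ax)) n_ax <- if (d == 1L) 801L else 121L
  ext <- resolution$grid_extent
  if (is.null(ext)) ext <- a + 8
  support <- uniform_tensor_grid(d, ext, n_ax)
  cls_w <- finite_model_class(lapply(seq_len(nrow(mus_w)), function(i) {
    gaussian_model(mus_w[i, ], diag(d))
  }))
  res <- blahut_arimoto(cls_w, support, tol = tol, max_iter = max_iter)
  ## map mixture back to original coordinates
  keep <- res$prior > 1e-12
  means <- w$inverse(mus_w[keep, , drop = FALSE])
  res$mixture <- de_gaussian_mixture(means, region$shape, res$prior[keep])
  res$class <- finite_model_class(lapply(seq_len(nrow(mus_w)), function(i) {
    gaussian_model(drop(w$inverse(mus_w[i, , drop = FALSE])), region$shape)
  }))
  res$whitening <- w
  res
}

## ---- closed-form sphere mixture (Gaussian case) ----------------------------

## largest ball radius for which the capacity-achieving input is uniform on
## the sphere (amplitude-constrained Gaussian channel); only the d = 2
## constant is shipped, other dimensions must be supplied by the caller.
SPHERE_RADIUS_TABLE <- c("2" = 2.454)

#' Closed-form single-sphere minimax mixture for a Gaussian-mean ellipsoid
#'
#' When the (whitened) region radius \eqn{a = \sqrt{\chi^2_d(1-\alpha)/n}}
#' does not exceed the critical radius \eqn{r_d} of the amplitude-constrained
#' Gaussian channel, the capacity-achieving input is uniform on the region
#' boundary and the minimax mixture has a closed form: for d = 1 the equal
#' two-point Gaussian mixture at the interval endpoints; for d = 2 the radial
#' density \eqn{q(x) \propto e^{-(r^2+a^2)/2} I_0(a r)} (whitened), which is
#' exactly normalized.
#'
#' @param region An \code{"ellipsoid_region"} with d = 1 or 2.
#' @param r_d Critical radius for the region's dimension; defaults to the
#'   shipped value 2.454 for d = 2, otherwise must be supplied (the
#'   condition flag is \code{NA} when unknown).
#' @return List with \code{estimate} (a \code{"density_estimate"} in original
#'   coordinates) and \code{condition_ok} (\code{TRUE}/\code{FALSE}/\code{NA}):
#'   whether \eqn{n \ge \chi^2_d(1-\alpha)/r_d^2}, i.e. \eqn{a \le r_d}.
#' @export
sphere_mixture_gaussian <- function(region, r_d = NULL) {
  stopifnot(inherits(region, "ellipsoid_region"))
  d <- region$d
  if (d > 2) stop("closed-form sphere mixture implemented for d <= 2")
  a <- sqrt(region$radius_sq)
  if (is.null(r_d)) {
    r_d <- unname(SPHERE_RADIUS_TABLE[as.character(d)])
    if (length(r_d) == 0 || is.na(r_d)) r_d <- NA_real_
  }
  condition_ok <- if (is.na(r_d)) NA else a <= r_d
  w <- whiten(region)
  if (d == 1L) {
    means <- w$inverse(matrix(c(-a, a), ncol = 1))
    est <- de_gaussian_mixture(means, region$shape, c(0.5, 0.5))
  } else {
    ldet <- determinant(region$shape, logarithm = TRUE)$modulus[1]
    f <- function(x) {
      z <- w$transform(to_points(x, 2))
      r <- sqrt(rowSums(z^2))
      ## log of (2pi)^-1 exp(-(r-a)^2/2) I0e(a r), Jacobian |Sigma|^-1/2
      -log(2 * pi) - 0.5 * ldet - 0.5 * (r - a)^2 +
        log(besselI(a * r, 0, expon.scaled = TRUE))
    }
    est <- new_density_estimate(f, kind = "gaussian_mixture", d = 2,
                                extra = list(sphere_radius = a, region = region))
  }
  list(estimate = est, condition_ok = condition_ok)
}

## ---- KL projections onto regions -------------------------------------------

#' KL projection of a Gaussian mean onto a confidence ellipsoid
#'
#' For equal-covariance Gaussians, \eqn{D(N(\mu,\Sigma)\|N(\mu',\Sigma))} is
#' half the squared Mahalanobis distance, so the KL-closest member of the
#' region is the Euclidean projection in whitened coordinates: interior means
#' are unchanged, exterior means are radially clipped to the boundary.
#'
#' @param mu Mean vector.
#' @param region An \code{"ellipsoid_region"}.
#' @return The projected mean vector.
#' @export
kl_project_gaussian <- function(mu, region) {
  stopifnot(inherits(region, "ellipsoid_region"))
  w <- whiten(region)
  z <- drop(w$transform(matrix(mu, nrow = 1)))
  r <- sqrt(sum(z^2))
  a <- sqrt(region$radius_sq)
  if (r <= a) return(as.numeric(mu))
  drop(w$inverse(matrix(z * a / r, nrow = 1)))
}

#' KL projection of a discrete distribution onto a box-simplex region
#'
#' Minimizes \eqn{D(p\|q)} over \eqn{\{q : l \le q \le u, \sum q_i = 1\}}.
#' By the KKT conditions the minimizer is \eqn{q_i = clip(p_i/\lambda, l_i,
#' u_i)} with the multiplier \eqn{\lambda} solved so the result sums to one
#' (monotone, solved by safeguarded root finding).
#'
#' @param p A \code{"discrete_distribution"}.
#' @param region A \code{"box_simplex_region"} on the same alphabet.
#' @return The projected \code{"discrete_distribution"}.
#' @export
kl_project_discrete <- function(p, region) {
  stopifnot(inherits(p, "discrete_distribution"),
            inherits(region, "box_simplex_region"))
  l <- region$lower; u <- region$upper
  if (p$m != length(l)) stop("alphabet sizes differ")
  pv <- p$probs
  if (all(pv >= l - 1e-12) && all(pv <= u + 1e-12)) {
    return(discrete_distribution(pmin(pmax(pv, l), u) /
                                   sum(pmin(pmax(pv, l), u))))
  }
  ssum <- function(lam) sum(pmin(pmax(pv / lam, l), u)) - 1
  lo <- 1e-12; hi <- 1e12
  if (ssum(lo) < 0 || ssum(hi) > 0) stop("KL projection infeasible: ",
                                         "box does not meet the simplex")
  lam <- stats::uniroot(ssum, c(lo, hi), tol = 1e-14)$root
  q <- pmin(pmax(pv / lam, l), u)
  ## distribute any residual slack over coordinates strictly inside bounds
  resid <- 1 - sum(q)
  if (abs(resid) > 0) {
    interior <- q > l + 1e-12 & q < u - 1e-12
    if (any(interior)) q[interior] <- q[interior] + resid / sum(interior)
  }
  discrete_distribution(q / sum(q))
}

## ---- constrained capacity (projected mixture) ------------------------------

#' Constrained capacity and the projected-mixture estimator
#'
#' Solves the constrained channel-capacity problem
#' \deqn{F = \sup_\phi \sum_\theta \phi(\theta)\,[D(p_\theta\|q_\phi) -
#'       \min_{\theta' \in \Theta_r} D(p_\theta\|p_{\theta'})]}
#' over a full model class by the alternating fixed-point updates
#' \eqn{\psi(\theta,x) = \phi(\theta)p_\theta(x)/\sum_\theta
#' \phi(\theta)p_\theta(x)} and \eqn{\phi(\theta) \propto \prod_x
#' \tilde\psi(\theta,x)^{p_\theta(x)}} with \eqn{\tilde\psi = \psi \cdot
#' p_{\theta^*}(x)/p_\theta(x)}. The resulting mixture \eqn{q_\Theta = \sum
#' \phi^*(\theta) p_\theta} bounds the regret against the best member of the
#' restricted class even when the truth lies outside it. With the identity
#' projection the problem reduces exactly to \code{\link{blahut_arimoto}}.
#'
#' @param full_class A \code{"finite_model_class"} covering the full
#'   parameter grid.
#' @param project Function mapping each model of \code{full_class} to its
#'   KL-closest member of the restricted class (e.g. built from
#'   \code{\link{kl_project_gaussian}} / \code{\link{kl_project_discrete}}).
#' @param support For Gaussian classes, an \code{"eval_grid"}.
#' @param tol Objective-gap tolerance in bits.
#' @param max_iter Iteration cap.
#' @param keep_psi Return the conditional weight table \eqn{\psi(\theta, x)}
#'   (can be large).
#' @return Object of class \code{"constrained_capacity_result"}:
#'   \code{f_bits}, \code{phi}, \code{mixture}, optionally \code{psi},
#'   \code{iterations}, \code{converged}, \code{projection_divergence}
#'   (bits, per model).
#' @export
constrained_capacity <- function(full_class, project, support = NULL,
                                 tol = 1e-9, max_iter = 10000L,
                                 keep_psi = FALSE) {
  stopifnot(inherits(full_class, "finite_model_class"))
  ch <- channel_matrix(full_class, support)
  proj_models <- lapply(full_class$models, project)
  proj_class <- finite_model_class(proj_models)
  chp <- channel_matrix(proj_class, ch$support)
  logP <- log(ch$P); logP[ch$P == 0] <- 0
  ## constraint term c_j = D(p_j || p*_j) on the shared support (nats)
  cj <- vapply(seq_len(nrow(ch$P)), function(j) {
    act <- ch$P[j, ] > 0
    if (any(chp$P[j, act] == 0)) return(Inf)
    sum(ch$P[j, act] * (logP[j, act] - log(chp$P[j, act])))
  }, numeric(1))
  if (any(!is.finite(cj))) stop("projection has infinite divergence for some model")
  ba <- ba_core(ch$P, tol = tol, max_iter = max_iter, exponent_offset = cj)
  mixture <- mixture_estimate(full_class, ba$prior)
  psi <- NULL
  if (keep_psi) {
    psi <- ba$prior * ch$P
    cs <- colSums(psi)
    psi <- sweep(psi, 2, ifelse(cs > 0, cs, 1), "/")
  }
  structure(list(f_bits = ba$capacity / LOG2,
                 phi = ba$prior,
                 mixture = mixture,
                 psi = psi,
                 per_model_score = (ba$D - cj) / LOG2,
                 projection_divergence = cj / LOG2,
                 iterations = ba$iterations,
                 converged = ba$converged,
                 monotone = ba$monotone,
                 class = full_class),
            class = "constrained_capacity_result")
}

#' @export
print.constrained_capacity_result <- function(x, ...) {
  cat("Constrained capacity: F =", signif(x$f_bits, 8), "bits,",
      x$iterations, "iterations",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}
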