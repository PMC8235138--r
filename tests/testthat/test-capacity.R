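test_that("Blahut-Arimoto recovers closed-form capacities", {
  # single model: zero capacity, degenerate prior
  one <- finite_model_class(list(discrete_distribution(c(0.4, 0.6))))
  r1 <- blahut_arimoto(one)
  expect_equal(r1$capacity_bits, 0, tolerance = 1e-12)
  expect_equal(r1$prior, 1)
  expect_equal(r1$mixture$probs, c(0.4, 0.6), tolerance = 1e-12)

  # noiseless binary channel: 1 bit, uniform prior
  two <- finite_model_class(list(discrete_distribution(c(1, 0)),
                                 discrete_distribution(c(0, 1))))
  r2 <- blahut_arimoto(two)
  expect_equal(r2$capacity_bits, 1, tolerance = 1e-9)
  expect_equal(r2$prior, c(0.5, 0.5), tolerance = 1e-9)
  expect_true(r2$converged)
  expect_true(r2$monotone)
})

test_that("Blahut-Arimoto matches an exhaustive prior grid search", {
  cls <- random_discrete_class(3, 4, seed = 21)
  res <- blahut_arimoto(cls, tol = 1e-10)
  oracle <- capacity_grid_oracle(cls, h = 1e-3)
  expect_lt(abs(res$capacity_bits - oracle), 1e-4)
  expect_gte(res$capacity_bits, oracle - 1e-8)  # grid can only undershoot
})

test_that("equalization holds at the capacity-achieving prior", {
  for (seed in 1:5) {
    cls <- random_discrete_class(4, 6, seed = 100 + seed)
    res <- blahut_arimoto(cls, tol = 1e-9, max_iter = 100000L)
    expect_true(res$converged)
    ## a model's divergence deficit is bounded by gap/weight, so the
    ## equalization check applies to models carrying non-negligible weight
    sup <- res$prior > 1e-3
    expect_true(any(sup))
    expect_lt(max(abs(res$per_model_divergence[sup] - res$capacity_bits)),
              1e-6)
    expect_true(all(res$per_model_divergence <= res$capacity_bits + 1e-8))
    expect_true(res$monotone)
  }
})

test_that("mixture minimax over a multinomial region behaves at the extremes", {
  p <- c(0.25, 0.35, 0.4)
  res <- mixture_minimax(box_simplex_region(p, p))
  expect_equal(res$capacity_bits, 0, tolerance = 1e-9)
  expect_equal(res$mixture$probs, p, tolerance = 1e-10)

  # worst-case divergence over a dense membership sample <= C + tol
  cnt <- c(18, 9, 6, 4)
  reg <- sison_glaz_intervals(cnt, 0.05)
  res <- mixture_minimax(reg, tol = 1e-9)
  qmix <- discrete_distribution(res$mixture$probs)
  set.seed(31)
  worst <- 0
  cls <- enumerate_vertices(reg)
  V <- do.call(rbind, lapply(cls$models, `[[`, "probs"))
  for (i in 1:500) {
    w <- stats::runif(nrow(V)); w <- w / sum(w)   # random hull member
    pm <- discrete_distribution(drop(crossprod(V, w)))
    worst <- max(worst, kl_discrete(pm, qmix))
  }
  expect_lte(worst, res$capacity_bits + 1e-6)
})

test_that("d = 1 interval mixture concentrates on the endpoints (grid-search oracle)", {
  reg <- gaussian_mean_region(0, 1, n = 4, alpha = 0.05)   # half-width 0.98
  res <- mixture_minimax(reg)
  expect_equal(res$prior, c(0.5, 0.5), tolerance = 1e-6)

  # brute-force search over endpoint weights on a 41-point grid: the
  # symmetric weight minimizes the worst-case of the two endpoint models
  a <- sqrt(reg$radius_sq)
  worst_of <- function(w) {
    q <- de_gaussian_mixture(c(-a, a), 1, c(w, 1 - w))
    max(kl_gaussian_vs_density(gaussian_model(-a, 1), q),
        kl_gaussian_vs_density(gaussian_model(a, 1), q))
  }
  ws <- seq(0.025, 0.975, length.out = 39)
  vals <- vapply(ws, worst_of, numeric(1))
  expect_equal(ws[which.min(vals)], 0.5, tolerance = 1e-9)
  expect_equal(res$capacity_bits, min(vals), tolerance = 2e-3)
})

test_that("closed-form sphere mixture: degenerate radius, d = 1 form, d = 2 oracle", {
  # radius -> 0 degenerates to the plug-in Gaussian
  reg <- gaussian_mean_region(1.3, 2, n = 10, alpha = 0.05)
  reg$radius_sq <- 1e-20
  sm <- sphere_mixture_gaussian(reg, r_d = 1)
  xs <- seq(-3, 5, length.out = 50)
  expect_equal(eval_log_density(sm$estimate, xs),
               stats::dnorm(xs, 1.3, sqrt(2), log = TRUE), tolerance = 1e-8)

  # d = 1: equal two-point mixture at the interval endpoints
  reg1 <- gaussian_mean_region(0.5, 1, n = 9, alpha = 0.05)
  a <- sqrt(reg1$radius_sq)
  sm1 <- sphere_mixture_gaussian(reg1, r_d = 1.06)
  direct <- log(0.5 * stats::dnorm(xs, 0.5 - a) + 0.5 * stats::dnorm(xs, 0.5 + a))
  expect_equal(eval_log_density(sm1$estimate, xs), direct, tolerance = 1e-10)
  expect_true(sm1$condition_ok)

  # d = 2: radial closed form vs seeded Monte-Carlo integration on the circle
  reg2 <- gaussian_mean_region(c(0.2, -0.1), diag(2), n = 2, alpha = 0.05)
  sm2 <- sphere_mixture_gaussian(reg2)
  expect_true(sm2$condition_ok)   # a = sqrt(5.99/2) = 1.73 < 2.454
  a2 <- sqrt(reg2$radius_sq)
  set.seed(77)
  th <- stats::runif(2e5, 0, 2 * pi)
  mus <- cbind(0.2 + a2 * cos(th), -0.1 + a2 * sin(th))
  pts <- matrix(stats::rnorm(40, sd = 1.4), ncol = 2) +
    matrix(c(0.2, -0.1), 20, 2, byrow = TRUE)
  for (i in 1:20) {
    dens <- stats::dnorm(pts[i, 1], mus[, 1]) * stats::dnorm(pts[i, 2], mus[, 2])
    mc <- mean(dens)
    se <- stats::sd(dens) / sqrt(length(dens))
    expect_lt(abs(exp(eval_log_density(sm2$estimate, pts[i, ])) - mc), 3 * se)
  }
})

test_that("constrained capacity reduces to plain capacity under the identity projection", {
  cls <- random_discrete_class(4, 5, seed = 55)
  ba <- blahut_arimoto(cls, tol = 1e-10)
  cc <- constrained_capacity(cls, project = identity, tol = 1e-10)
  expect_equal(cc$f_bits, ba$capacity_bits, tolerance = 1e-8)
  expect_equal(cc$phi, ba$prior, tolerance = 1e-5)

  one <- finite_model_class(list(discrete_distribution(c(0.3, 0.7))))
  expect_equal(constrained_capacity(one, identity)$f_bits, 0, tolerance = 1e-12)
})

test_that("constrained capacity matches an exhaustive grid search of the objective", {
  set.seed(66)
  full <- random_discrete_class(3, 4, seed = 66)
  restricted <- list(full$models[[2]],
                     discrete_distribution(c(0.4, 0.3, 0.2, 0.1)))
  project <- function(p) {
    divs <- vapply(restricted, function(r) kl_discrete(p, r, "nats"), numeric(1))
    restricted[[which.min(divs)]]
  }
  cc <- constrained_capacity(full, project, tol = 1e-10)
  offs <- vapply(full$models, function(p) {
    min(vapply(restricted, function(r) kl_discrete(p, r, "nats"), numeric(1)))
  }, numeric(1))
  oracle <- capacity_grid_oracle(full, h = 1e-3, offsets = offs)
  expect_lt(abs(cc$f_bits - oracle), 1e-4)
  # psi columns are conditional distributions over models
  cc2 <- constrained_capacity(full, project, keep_psi = TRUE)
  expect_true(all(abs(colSums(cc2$psi) - 1) < 1e-9))
})

test_that("KL projections onto regions are exact", {
  # Gaussian: interior fixed point, 1-d clipping, 2-d vs constrained optimizer
  reg <- gaussian_mean_region(0, 1, n = 4, alpha = 0.05)
  a <- sqrt(reg$radius_sq)
  expect_equal(kl_project_gaussian(0.3, reg), 0.3)
  expect_equal(kl_project_gaussian(a + 2, reg), a, tolerance = 1e-12)

  Sigma <- matrix(c(2, 0.5, 0.5, 1), 2)
  reg2 <- gaussian_mean_region(c(0.5, -0.5), Sigma, n = 5, alpha = 0.1)
  mu <- c(3, 2)
  proj <- kl_project_gaussian(mu, reg2)
  expect_true(in_region(reg2, proj, tol = 1e-8))
  # oracle: minimize the Mahalanobis distance over the boundary angle
  w <- whiten(reg2)
  obj <- function(th) {
    cand <- drop(w$inverse(sqrt(reg2$radius_sq) * c(cos(th), sin(th))))
    dd <- mu - cand
    drop(t(dd) %*% solve(Sigma, dd))
  }
  best <- stats::optimize(obj, c(-pi, pi), tol = 1e-12)
  cand <- drop(w$inverse(sqrt(reg2$radius_sq) *
                           c(cos(best$minimum), sin(best$minimum))))
  expect_equal(proj, cand, tolerance = 1e-5)

  # discrete: interior fixed point
  regd <- box_simplex_region(c(0.1, 0.1, 0.1), c(0.8, 0.8, 0.8))
  p_in <- discrete_distribution(c(0.3, 0.3, 0.4))
  expect_equal(kl_project_discrete(p_in, regd)$probs, p_in$probs,
               tolerance = 1e-12)

  # m = 2 with a binding upper bound: closed-form clip
  regb <- box_simplex_region(c(0, 0), c(0.6, 1))
  p2 <- discrete_distribution(c(0.9, 0.1))
  expect_equal(kl_project_discrete(p2, regb)$probs, c(0.6, 0.4),
               tolerance = 1e-9)

  # m = 3 vs dense grid search over the feasible polytope
  p3 <- discrete_distribution(c(0.7, 0.2, 0.1))
  regc <- box_simplex_region(c(0.15, 0.15, 0.15), c(0.5, 0.5, 0.5))
  proj3 <- kl_project_discrete(p3, regc)
  g <- expand.grid(q1 = seq(0.15, 0.5, 1e-3), q2 = seq(0.15, 0.5, 1e-3))
  g$q3 <- 1 - g$q1 - g$q2
  g <- g[g$q3 >= 0.15 & g$q3 <= 0.5, ]
  dv <- p3$probs[1] * log(p3$probs[1] / g$q1) +
    p3$probs[2] * log(p3$probs[2] / g$q2) +
    p3$probs[3] * log(p3$probs[3] / g$q3)
  expect_lt(kl_discrete(p3, proj3, "nats"), min(dv) + 1e-5)
})
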