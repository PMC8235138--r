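# straightforward independent re-implementation of the Gale recipe, kept
# deliberately separate from the package code path
sgt_oracle <- function(counts) {
  n <- sum(counts)
  m <- length(counts)
  seen <- which(counts > 0)
  freq <- counts[seen]
  r <- sort(unique(freq))
  Nr <- sapply(r, function(v) sum(freq == v))
  K <- length(r)
  Z <- numeric(K)
  for (k in 1:K) {
    q <- if (k == 1) 0 else r[k - 1]
    t <- if (k == K) 2 * r[K] - r[K - 1] else r[k + 1]
    Z[k] <- 2 * Nr[k] / (t - q)
  }
  fit <- stats::lm(log(Z) ~ log(r))
  co <- stats::coef(fit)
  S <- function(v) exp(co[[1]] + co[[2]] * log(v))
  rstar <- numeric(K)
  use_lgt <- FALSE
  for (k in 1:K) {
    lgt <- (r[k] + 1) * S(r[k] + 1) / S(r[k])
    next_nr <- if (k < K && r[k + 1] == r[k] + 1) Nr[k + 1] else 0
    if (!use_lgt) {
      if (next_nr == 0) {
        use_lgt <- TRUE
      } else {
        turing <- (r[k] + 1) * next_nr / Nr[k]
        sdv <- sqrt((r[k] + 1)^2 * (next_nr / Nr[k]^2) * (1 + next_nr / Nr[k]))
        if (abs(turing - lgt) <= 1.65 * sdv) use_lgt <- TRUE
        else rstar[k] <- turing
      }
    }
    if (use_lgt) rstar[k] <- lgt
  }
  p0 <- if (r[1] == 1) Nr[1] / n else 0
  seen_p <- (1 - p0) * rstar[match(freq, r)] / sum(Nr * rstar)
  out <- numeric(m)
  out[seen] <- seen_p
  if (length(seen) < m) out[-seen] <- p0 / (m - length(seen))
  out / sum(out)
}

test_that("MLE and add-constant estimators follow their closed forms", {
  expect_equal(mle_counts(c(2, 0, 2))$probs, c(0.5, 0, 0.5))
  expect_equal(mle_counts(c(0, 7))$probs, c(0, 1))
  expect_error(mle_counts(c(0, 0)), "n = 0")

  p <- zipf_pmf(3, 1)
  expect_identical(kl_discrete(p, mle_counts(c(2, 0, 2))), Inf)

  expect_equal(add_constant(c(1, 0), 0.5)$probs, c(0.75, 0.25))
  expect_equal(add_constant(c(0, 0, 0), 0.5)$probs, rep(1 / 3, 3))
  # Laplace rule cross-check on a fixture
  cnt <- c(5, 3, 0, 2)
  expect_equal(add_constant(cnt, 1)$probs, (cnt + 1) / (10 + 4))
  expect_error(add_constant(c(1, 1), 0), "positive")
})

test_that("Simple Good-Turing matches an independent Gale-recipe oracle", {
  # fixed 20-symbol fixture with a realistic count profile
  counts <- c(9, 6, 4, 4, 3, 2, 2, 2, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0)
  g <- simple_good_turing(counts)
  expect_equal(g$probs, sgt_oracle(counts), tolerance = 1e-10)
  expect_equal(sum(g$probs), 1, tolerance = 1e-12)
  expect_true(all(g$probs > 0))            # N1 > 0 and unseen symbols exist
  expect_equal(attr(g, "p0"), 4 / sum(counts))

  # random fixtures agree too
  set.seed(12)
  for (i in 1:5) {
    cnt <- drop(stats::rmultinom(1, 60, zipf_pmf(40, 1.3)$probs))
    expect_equal(simple_good_turing(cnt)$probs, sgt_oracle(cnt),
                 tolerance = 1e-10)
  }

  # no singletons: zero unseen mass
  g2 <- simple_good_turing(c(4, 2, 2, 0, 0))
  expect_equal(attr(g2, "p0"), 0)
  expect_equal(sum(g2$probs[4:5]), 0)

  # saturated alphabet with singletons: flagged, renormalized over seen
  g3 <- simple_good_turing(c(3, 2, 1))
  expect_true(attr(g3, "saturated"))
  expect_equal(sum(g3$probs), 1, tolerance = 1e-12)
})

test_that("leave-one-out class structure: counts, multiplicities, members", {
  # n = 2 identical samples: a single distinct model
  cls <- loo_class(c(2, 0, 0), base = "kt")
  expect_equal(length(cls$models$models), 1L)
  expect_equal(sum(cls$multiplicities), 2)

  cnt <- c(5, 3, 1, 0, 1)
  cls <- loo_class(cnt, base = "good_turing")
  expect_lte(length(cls$models$models), sum(cnt > 0))
  expect_equal(sum(cls$multiplicities), sum(cnt))

  # add-constant base: each member equals the estimator on decremented counts
  cls2 <- loo_class(cnt, base = "add_constant", const = 0.5)
  for (k in seq_along(cls2$left_out)) {
    dec <- cnt
    dec[cls2$left_out[k]] <- dec[cls2$left_out[k]] - 1
    expect_equal(cls2$models$models[[k]]$probs, add_constant(dec, 0.5)$probs,
                 tolerance = 1e-14)
  }
  expect_error(loo_class(c(1, 0)), "n >= 2")
})

test_that("LOO aggregation: NML and uniform mixture", {
  cnt <- c(4, 2, 0)
  cls <- loo_class(cnt, base = "kt")
  res <- loo_nml(cls)
  # hand-computed Z: symbol-wise max over the two distinct models
  m1 <- add_constant(c(3, 2, 0), 0.5)$probs
  m2 <- add_constant(c(4, 1, 0), 0.5)$probs
  z_hand <- sum(pmax(m1, m2))
  expect_equal(res$z, z_hand, tolerance = 1e-12)
  expect_gte(res$gamma_bits, 0)
  expect_equal(res$estimate$probs, pmax(m1, m2) / z_hand, tolerance = 1e-12)

  # single-model class: base estimate unchanged, Gamma = 0
  cls1 <- loo_class(c(2, 0), base = "kt")
  r1 <- loo_nml(cls1)
  expect_equal(r1$gamma_bits, 0, tolerance = 1e-12)
  expect_equal(r1$estimate$probs, add_constant(c(1, 0), 0.5)$probs)
  expect_equal(uniform_mixture(cls1)$probs, add_constant(c(1, 0), 0.5)$probs)

  # distinct-uniform average of complementary point masses
  toy <- structure(list(
    base_name = "toy",
    models = finite_model_class(list(discrete_distribution(c(1, 0)),
                                     discrete_distribution(c(0, 1)))),
    multiplicities = c(3, 1), left_out = c(1, 2)), class = "loo_class")
  expect_equal(uniform_mixture(toy, "distinct")$probs, c(0.5, 0.5))
  expect_equal(uniform_mixture(toy, "multiplicity")$probs, c(0.75, 0.25))

  # convexity: mixture KL to truth <= worst member KL
  p <- zipf_pmf(3, 1)
  cls3 <- loo_class(c(4, 2, 1), base = "kt")
  mix_kl <- kl_discrete(p, uniform_mixture(cls3))
  member_kl <- vapply(cls3$models$models, function(q) kl_discrete(p, q),
                      numeric(1))
  expect_lte(mix_kl, max(member_kl) + 1e-12)
})

test_that("natural oracle is the KL-optimal count-group-constant assignment", {
  p <- discrete_distribution(c(0.5, 0.3, 0.2))

  # all counts distinct: oracle recovers the truth exactly
  po <- natural_oracle(p, c(3, 2, 1))
  expect_equal(po$probs, p$probs, tolerance = 1e-14)
  expect_equal(kl_discrete(p, po), 0, tolerance = 1e-12)

  # no samples: a single group, uniform over the alphabet
  expect_equal(natural_oracle(p, c(0, 0, 0))$probs, rep(1 / 3, 3))

  # one tied group {2, 3}: group average beats any other constant on a grid
  cnt <- c(2, 1, 1)
  po2 <- natural_oracle(p, cnt)
  expect_equal(po2$probs, c(0.5, 0.25, 0.25), tolerance = 1e-14)
  oracle_kl <- kl_discrete(p, po2, "nats")
  for (c2 in seq(0.01, 0.49, 1e-3)) {   # mass per tied symbol
    q <- discrete_distribution(c(1 - 2 * c2, c2, c2))
    expect_gte(kl_discrete(p, q, "nats"), oracle_kl - 1e-12)
  }
})

test_that("proper-estimator diagnostic: add-constant passes, MLE fails finiteness", {
  p <- zipf_pmf(20, 1.01)
  diag_kt <- proper_diagnostic("add_constant", p, n_grid = c(10, 20, 40),
                               reps = 1500, seed = 5, const = 0.5)
  expect_true(diag_kt$finite_ok)
  expect_true(diag_kt$nonneg_ok)
  expect_true(diag_kt$monotone_ok)
  expect_true(all(diag_kt$delta$delta >= -2 * diag_kt$delta$se))

  diag_mle <- proper_diagnostic("mle", p, n_grid = 10, reps = 300, seed = 6)
  expect_false(diag_mle$finite_ok)   # unseen symbols give unbounded KL
  expect_lt(diag_mle$delta$finite_fraction, 1)
})
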