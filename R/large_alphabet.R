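## Large-alphabet probability estimation: base estimators (MLE, add-constant
## / Krichevsky-Trofimov, Simple Good-Turing), the leave-one-out model class,
## NML and uniform-mixture aggregation over it, the natural oracle, and the
## proper-estimator diagnostic.

#' Symbol counts over a known alphabet
#'
#' @param counts Nonnegative integer count per symbol (length m, the alphabet
#'   size; unseen symbols have count 0).
#' @return Object of class \code{"count_vector"} with fields \code{counts},
#'   \code{n} (total) and \code{m}.
#' @export
count_vector <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 1) stop("alphabet size must be >= 1")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  structure(list(counts = counts, n = sum(counts), m = length(counts)),
            class = "count_vector")
}

#' @export
print.count_vector <- function(x, ...) {
  cat("Count vector: n =", x$n, "over m =", x$m, "symbols (",
      sum(x$counts > 0), "observed )\n")
  invisible(x)
}

as_count_vector <- function(c) {
  if (inherits(c, "count_vector")) c else count_vector(c)
}

#' Maximum-likelihood (empirical) distribution from counts
#'
#' \eqn{\hat p(i) = n_i / n}; assigns zero probability to unseen symbols, so
#' its KL divergence from a fully supported truth is unbounded.
#'
#' @param c A \code{"count_vector"} (or plain counts).
#' @return A \code{"discrete_distribution"}.
#' @export
mle_counts <- function(c) {
  c <- as_count_vector(c)
  if (c$n < 1) stop("MLE undefined for n = 0")
  discrete_distribution(c$counts / c$n)
}

#' Add-constant (Laplace-family) estimator
#'
#' \eqn{q(i) = (n_i + \delta)/(n + m\delta)}. \code{const = 1/2} is the
#' Krichevsky-Trofimov estimator, \code{const = 1} the Laplace rule.
#'
#' @param c A \code{"count_vector"} (or plain counts).
#' @param const Positive pseudo-count added to every symbol (default 1/2).
#' @return A \code{"discrete_distribution"}.
#' @export
add_constant <- function(c, const = 0.5) {
  c <- as_count_vector(c)
  if (const <= 0) stop("const must be positive")
  discrete_distribution((c$counts + const) / (c$n + c$m * const))
}

#' Simple Good-Turing estimator
#'
#' Good-Turing estimation with Gale's "Simple" smoothing: the
#' frequency-of-frequencies \eqn{N_r} are smoothed by a log-log linear fit to
#' averaged counts \eqn{Z_r = 2N_r/(t-q)} (neighbor gaps \eqn{q < r < t});
#' adjusted counts \eqn{r^*} use the raw Turing estimate
#' \eqn{(r+1)N_{r+1}/N_r} for small \eqn{r} and switch permanently to the
#' smoothed estimate once the two differ by less than 1.65 standard
#' deviations (or the Turing estimate is undefined). The unseen mass
#' \eqn{P_0 = N_1/n} is split uniformly over the \eqn{m - D} unseen symbols
#' (the alphabet size \eqn{m} is known); seen symbols share \eqn{1 - P_0}
#' proportionally to \eqn{r^*}.
#'
#' @param c A \code{"count_vector"} (or plain counts).
#' @return A \code{"discrete_distribution"}; attribute \code{"p0"} carries the
#'   unseen mass and attribute \code{"saturated"} flags the degenerate case
#'   where every symbol was observed yet \eqn{N_1 > 0} (the unseen mass is
#'   then folded back proportionally).
#' @references Gale, W.A. and Sampson, G. (1995) Good-Turing frequency
#'   estimation without tears. J. Quantitative Linguistics 2, 217-237.
#' @export
simple_good_turing <- function(c) {
  c <- as_count_vector(c)
  if (c$n < 1) stop("Good-Turing undefined for n = 0")
  counts <- c$counts
  seen <- counts > 0
  D <- sum(seen)
  tab <- table(counts[seen])
  r <- as.numeric(names(tab))
  Nr <- as.numeric(tab)
  K <- length(r)
  ## smoothed proxy S(r) from the log-log fit of Z_r
  if (K >= 2) {
    qn <- c(0, r[-K])
    tn <- c(r[-1], 2 * r[K] - r[K - 1])
    Zr <- 2 * Nr / (tn - qn)
    xs <- log(r); ys <- log(Zr)
    b <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
    aa <- mean(ys) - b * mean(xs)
  } else {
    b <- -1; aa <- 0  # single frequency: smoothed adjusted count reduces to r
  }
  s_fun <- function(rr) exp(aa + b * log(rr))
  rstar <- numeric(K)
  switched <- FALSE
  for (k in seq_len(K)) {
    rk <- r[k]
    lgt <- (rk + 1) * s_fun(rk + 1) / s_fun(rk)
    nr1 <- if (k < K && r[k + 1] == rk + 1) Nr[k + 1] else 0
    if (!switched && nr1 > 0) {
      turing <- (rk + 1) * nr1 / Nr[k]
      sd_t <- sqrt((rk + 1)^2 * (nr1 / Nr[k]^2) * (1 + nr1 / Nr[k]))
      if (abs(turing - lgt) > 1.65 * sd_t) {
        rstar[k] <- turing
      } else {
        switched <- TRUE
        rstar[k] <- lgt
      }
    } else {
      switched <- TRUE
      rstar[k] <- lgt
    }
  }
  N1 <- if (r[1] == 1) Nr[1] else 0
  p0 <- N1 / c$n
  tot <- sum(Nr * rstar)
  pr_seen <- (1 - p0) * rstar / tot       # per-symbol prob by frequency class
  probs <- numeric(c$m)
  probs[seen] <- pr_seen[match(counts[seen], r)]
  saturated <- FALSE
  if (D < c$m) {
    probs[!seen] <- p0 / (c$m - D)
  } else if (p0 > 0) {
    saturated <- TRUE                      # no unseen symbols to carry P0
    probs[seen] <- probs[seen] / sum(probs[seen])
  }
  out <- discrete_distribution(probs / sum(probs))
  attr(out, "p0") <- p0
  attr(out, "saturated") <- saturated
  out
}

## estimator registry used by the LOO class, the diagnostic and the harness
base_estimator <- function(name, const = 0.5) {
  switch(name,
         mle = function(c) mle_counts(c),
         kt = function(c) add_constant(c, 0.5),
         laplace = function(c) add_constant(c, 1),
         add_constant = function(c) add_constant(c, const),
         good_turing = function(c) simple_good_turing(c),
         stop("unknown base estimator: ", name))
}

#' Leave-one-out model class
#'
#' For each distinct observed symbol \eqn{s}, the base estimate refit on the
#' counts with one occurrence of \eqn{s} removed. Each left-out sample index
#' contributes one class member, so the multiplicity of the model for symbol
#' \eqn{s} is \eqn{n_s}; identical models are deduplicated with their
#' multiplicities merged.
#'
#' @param c A \code{"count_vector"} (or plain counts) with \eqn{n \ge 2}.
#' @param base Base estimator name: \code{"good_turing"} (default),
#'   \code{"kt"}, \code{"laplace"}, \code{"add_constant"}, \code{"mle"}.
#' @param const Pseudo-count when \code{base = "add_constant"}.
#' @return Object of class \code{"loo_class"}: \code{base_name},
#'   \code{models} (a \code{"finite_model_class"}), \code{multiplicities},
#'   \code{left_out} (the removed symbol per model).
#' @export
loo_class <- function(c, base = "good_turing", const = 0.5) {
  c <- as_count_vector(c)
  if (c$n < 2) stop("leave-one-out class requires n >= 2")
  fit <- base_estimator(base, const)
  symbols <- which(c$counts > 0)
  models <- vector("list", length(symbols))
  for (k in seq_along(symbols)) {
    c2 <- c$counts
    c2[symbols[k]] <- c2[symbols[k]] - 1
    models[[k]] <- fit(count_vector(c2))
  }
  mult <- c$counts[symbols]
  dup <- duplicated(lapply(models, `[[`, "probs"))
  if (any(dup)) {
    key <- match(lapply(models, `[[`, "probs"),
                 lapply(models[!dup], `[[`, "probs"))
    mult <- as.numeric(tapply(mult, key, sum))
    symbols <- symbols[!dup]
    models <- models[!dup]
  }
  structure(list(base_name = base,
                 models = finite_model_class(models,
                                             labels = paste0("-", symbols)),
                 multiplicities = mult,
                 left_out = symbols),
            class = "loo_class")
}

#' @export
print.loo_class <- function(x, ...) {
  cat("Leave-one-out class (", x$base_name, "): ",
      length(x$models$models), " distinct models, n = ",
      sum(x$multiplicities), "\n", sep = "")
  invisible(x)
}

#' NML estimator over a leave-one-out class
#'
#' Normalized maximum likelihood (symbol-wise maximum over the class,
#' normalized over the alphabet) applied to the leave-one-out models.
#'
#' @param cls A \code{"loo_class"}.
#' @return An \code{"nml_result"} (see \code{\link{nml_finite}}).
#' @export
loo_nml <- function(cls) {
  stopifnot(inherits(cls, "loo_class"))
  nml_finite(cls$models)
}

#' Uniform average over a leave-one-out class
#'
#' @param cls A \code{"loo_class"}.
#' @param weighting \code{"multiplicity"} (default): every left-out sample
#'   index contributes equally, so each distinct model is weighted by its
#'   multiplicity; \code{"distinct"}: equal weight per distinct model.
#' @return A \code{"discrete_distribution"}.
#' @export
uniform_mixture <- function(cls, weighting = c("multiplicity", "distinct")) {
  stopifnot(inherits(cls, "loo_class"))
  weighting <- match.arg(weighting)
  w <- if (weighting == "multiplicity") cls$multiplicities
       else rep(1, length(cls$models$models))
  w <- w / sum(w)
  probs <- Reduce(`+`, Map(function(p, wi) wi * p$probs, cls$models$models,
                           as.list(w)))
  discrete_distribution(probs / sum(probs))
}

#' Natural oracle: count-group-constant optimum knowing the truth
#'
#' The oracle knows the true distribution but must assign equal probability
#' to symbols sharing an observed count (including count zero). The
#' KL-optimal such assignment gives every symbol in a count group the group's
#' averaged true probability; its divergence lower-bounds any estimator that,
#' like all count-based estimators, is a function of the counts alone.
#'
#' @param p_true A \code{"discrete_distribution"}.
#' @param c A \code{"count_vector"} on the same alphabet.
#' @return A \code{"discrete_distribution"}.
#' @export
natural_oracle <- function(p_true, c) {
  stopifnot(inherits(p_true, "discrete_distribution"))
  c <- as_count_vector(c)
  if (p_true$m != c$m) stop("alphabet sizes differ")
  grp <- match(c$counts, sort(unique(c$counts)))
  gmass <- tapply(p_true$probs, grp, sum)
  gsize <- tabulate(grp)
  discrete_distribution(as.numeric(gmass[grp]) / gsize[grp])
}

#' Proper-estimator diagnostic
#'
#' Monte-Carlo check of the three properness conditions for a count-based
#' estimator under a known truth: finite expected divergence, eventually
#' nonnegative expected improvement \eqn{\Delta_p(n) = E[D(p\|q_n)] -
#' E[D(p\|q_{n+1})]}, and non-increasing \eqn{\Delta_p(n)}. Reported with
#' standard errors; draws at \eqn{n} and \eqn{n+1} use independent seeded
#' streams.
#'
#' @param base Base estimator name (see \code{\link{loo_class}}).
#' @param p_true A \code{"discrete_distribution"}.
#' @param n_grid Increasing sample sizes at which to evaluate
#'   \eqn{\Delta_p(n)}.
#' @param reps Monte-Carlo replicates per sample size (>= 1000).
#' @param seed Master seed.
#' @param const Pseudo-count for \code{base = "add_constant"}.
#' @return Object of class \code{"proper_diagnostic"}: a data frame
#'   \code{delta} (n, delta, se, finite_fraction at n) plus logical summary
#'   flags \code{finite_ok}, \code{nonneg_ok}, \code{monotone_ok}
#'   (within 2 standard errors).
#' @export
proper_diagnostic <- function(base, p_true, n_grid, reps = 2000L, seed = 1L,
                              const = 0.5) {
  stopifnot(inherits(p_true, "discrete_distribution"), reps >= 1)
  fit <- base_estimator(base, const)
  n_grid <- sort(unique(as.integer(n_grid)))
  sizes <- sort(unique(c(n_grid, n_grid + 1L)))
  set.seed(seed)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, length(sizes))
  mean_kl <- se_kl <- fin <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    set.seed(stream_seeds[i])
    kls <- numeric(reps)
    for (r in seq_len(reps)) {
      cnt <- count_vector(drop(stats::rmultinom(1, sizes[i], p_true$probs)))
      kls[r] <- kl_discrete(p_true, fit(cnt), unit = "bits")
    }
    ok <- is.finite(kls)
    fin[i] <- mean(ok)
    mean_kl[i] <- if (any(ok)) mean(kls[ok]) else Inf
    se_kl[i] <- if (sum(ok) > 1) stats::sd(kls[ok]) / sqrt(sum(ok)) else NA
  }
  idx <- match(n_grid, sizes)
  idx1 <- match(n_grid + 1L, sizes)
  delta <- mean_kl[idx] - mean_kl[idx1]
  se_d <- sqrt(se_kl[idx]^2 + se_kl[idx1]^2)
  tab <- data.frame(n = n_grid, delta = delta, se = se_d,
                    finite_fraction = fin[idx])
  finite_ok <- all(fin == 1)
  nonneg_ok <- finite_ok && all(delta >= -2 * se_d)
  monotone_ok <- finite_ok &&
    (length(delta) < 2 ||
       all(diff(delta) <= 2 * sqrt(se_d[-1]^2 + se_d[-length(se_d)]^2)))
  structure(list(delta = tab, finite_ok = finite_ok, nonneg_ok = nonneg_ok,
                 monotone_ok = monotone_ok, base_name = base, reps = reps),
            class = "proper_diagnostic")
}

#' @export
print.proper_diagnostic <- function(x, ...) {
  cat("Proper-estimator diagnostic for '", x$base_name, "' (",
      x$reps, " reps):\n", sep = "")
  print(x$delta, row.names = FALSE)
  cat("  finite:", x$finite_ok, " nonnegative:", x$nonneg_ok,
      " non-increasing:", x$monotone_ok, "\n")
  invisible(x)
}
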