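## Simulation harness: the paper-style evaluation protocol. For each sample
## size, k seeded replicates are drawn; every estimator is fit to the same
## replicate (paired evaluation, which reduces comparison variance) and
## scored against the true generator by KL divergence or by per-draw regret
## against the natural oracle. Mean, variance and worst-case (max over
## replicates) are reported per estimator and sample size.

#' Experiment configuration
#'
#' @param generator A \code{"generator_spec"} (the truth).
#' @param n_grid Sample sizes to sweep.
#' @param k Replicates per sample size.
#' @param estimators Character vector of estimator names. Discrete families:
#'   \code{"truth"}, \code{"mle"}, \code{"kt"}, \code{"laplace"},
#'   \code{"good_turing"}, \code{"loo_uniform"}, \code{"loo_nml"},
#'   \code{"mixture_sg"}, \code{"nml_sg"}. Gaussian: \code{"truth"},
#'   \code{"mle"}, \code{"js"}, \code{"mixture"}, \code{"nml"},
#'   \code{"projected"}.
#' @param alpha Confidence level parameter for region-based estimators.
#' @param metric \code{"kl"} or \code{"regret_vs_oracle"} (discrete only:
#'   per-draw difference from the natural oracle's divergence).
#' @param unit Reporting unit (\code{"bits"} default).
#' @param master_seed Master seed; replicate seeds are drawn from it.
#' @param loo_base Base estimator for the leave-one-out estimators.
#' @param gh_nodes Gauss-Hermite nodes per axis for continuous divergences.
#' @param keep_values Keep the full replicate-by-estimator value matrix.
#' @return Object of class \code{"experiment_config"}.
#' @export
experiment_config <- function(generator, n_grid, k, estimators,
                              alpha = 0.05, metric = c("kl",
                                                       "regret_vs_oracle"),
                              unit = "bits", master_seed = 1L,
                              loo_base = "good_turing", gh_nodes = 200L,
                              keep_values = FALSE) {
  stopifnot(inherits(generator, "generator_spec"), k >= 1,
            length(n_grid) >= 1, length(estimators) >= 1)
  metric <- match.arg(metric)
  if (metric == "regret_vs_oracle" && generator$family == "gaussian")
    stop("the natural-oracle regret metric is defined for discrete families")
  structure(list(generator = generator, n_grid = as.integer(n_grid),
                 k = as.integer(k), estimators = estimators, alpha = alpha,
                 metric = metric, unit = resolve_unit(unit),
                 master_seed = as.integer(master_seed), loo_base = loo_base,
                 gh_nodes = as.integer(gh_nodes),
                 keep_values = isTRUE(keep_values)),
            class = "experiment_config")
}

## per-family fitter registries ----------------------------------------------

discrete_fitters <- function(cfg) {
  p_true <- cfg$generator$pmf
  lapply(stats::setNames(cfg$estimators, cfg$estimators), function(nm) {
    switch(nm,
      truth = function(cnt) p_true,
      mle = , kt = , laplace = , good_turing = {
        f <- base_estimator(nm)
        function(cnt) f(cnt)
      },
      loo_uniform = function(cnt)
        uniform_mixture(loo_class(cnt, cfg$loo_base)),
      loo_nml = function(cnt)
        discrete_distribution(loo_nml(loo_class(cnt, cfg$loo_base))$estimate$probs),
      mixture_sg = function(cnt) {
        res <- mixture_minimax(sison_glaz_intervals(cnt, cfg$alpha))
        discrete_distribution(res$mixture$probs)
      },
      nml_sg = function(cnt) {
        cls <- enumerate_vertices(sison_glaz_intervals(cnt, cfg$alpha))
        discrete_distribution(nml_finite(cls)$estimate$probs)
      },
      stop("unknown discrete estimator: ", nm))
  })
}

gaussian_fitters <- function(cfg) {
  truth <- cfg$generator$model
  Sigma <- truth$cov
  d <- truth$d
  region_of <- function(x, n) gaussian_mean_region(colMeans(x), Sigma, n,
                                                   cfg$alpha)
  lapply(stats::setNames(cfg$estimators, cfg$estimators), function(nm) {
    switch(nm,
      truth = function(x, n) de_gaussian(truth),
      mle = function(x, n) mle_density_gaussian(colMeans(x), Sigma),
      js = function(x, n) {
        mu <- james_stein(colMeans(x), mean(diag(Sigma)), n)
        de_gaussian(gaussian_model(mu, Sigma))
      },
      mixture = function(x, n)
        sphere_mixture_gaussian(region_of(x, n))$estimate,
      nml = function(x, n) {
        if (d != 1) stop("interval NML is one-dimensional")
        reg <- region_of(x, n)
        nml_gaussian_interval(reg$center, sqrt(reg$radius_sq),
                              sqrt(Sigma[1, 1]))$estimate
      },
      projected = function(x, n)
        projected_mixture_interval(region_of(x, n))$mixture,
      stop("unknown Gaussian estimator: ", nm))
  })
}

#' Projected-mixture estimator for a one-dimensional Gaussian interval
#'
#' Builds the full mean grid (a symmetric grid extending four interval
#' widths beyond the confidence interval, spaced at 1/100 of the width),
#' projects each grid mean onto the interval and solves the constrained
#' capacity problem; the resulting mixture places mass outside the interval,
#' trading average accuracy for robustness when the truth escapes the region.
#'
#' @param region A one-dimensional \code{"ellipsoid_region"}.
#' @param extent_widths Grid extent beyond the interval, in interval widths.
#' @param spacing_frac Grid spacing as a fraction of the interval width.
#' @param tol,max_iter Solver controls.
#' @return A \code{"constrained_capacity_result"} (mixture in original
#'   coordinates).
#' @export
projected_mixture_interval <- function(region, extent_widths = 4,
                                       spacing_frac = 0.01, tol = 1e-7,
                                       max_iter = 5000L) {
  stopifnot(inherits(region, "ellipsoid_region"), region$d == 1L)
  a <- sqrt(region$radius_sq)
  width <- 2 * a
  ext <- a + extent_widths * width
  mus_w <- seq(-ext, ext, by = spacing_frac * width)
  w <- whiten(region)
  wreg <- w$region
  cls <- finite_model_class(lapply(mus_w, function(m) gaussian_model(m, diag(1))))
  support <- uniform_tensor_grid(1L, ext + 8, 1201L)
  res <- constrained_capacity(cls,
                              project = function(gm)
                                gaussian_model(kl_project_gaussian(gm$mean,
                                                                   wreg),
                                               diag(1)),
                              support = support, tol = tol,
                              max_iter = max_iter)
  keep <- res$phi > 1e-12
  res$mixture <- de_gaussian_mixture(w$inverse(matrix(mus_w[keep], ncol = 1)),
                                     region$shape, res$phi[keep])
  res
}

#' Run a simulation experiment
#'
#' Executes the replicate protocol of \code{cfg}: per sample size, draw
#' \code{k} seeded samples, fit every estimator to the same draw, and score
#' it against the truth (KL, or per-draw regret relative to the natural
#' oracle). Replicates on which an estimator has unbounded divergence are
#' excluded from mean/variance and counted; estimator errors likewise.
#'
#' @param cfg An \code{"experiment_config"}.
#' @return Object of class \code{"experiment_report"} with a summary data
#'   frame (estimator, n, mean, variance, worst_case, worst_index,
#'   infinite_count, excluded) and, when requested, per-replicate values.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  gaussian <- cfg$generator$family == "gaussian"
  fitters <- if (gaussian) gaussian_fitters(cfg) else discrete_fitters(cfg)
  scheme <- quadrature_spec(gh_nodes = cfg$gh_nodes)
  p_true <- if (gaussian) cfg$generator$model else cfg$generator$pmf
  set.seed(cfg$master_seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max - 1L,
                                cfg$k * length(cfg$n_grid)),
                     nrow = cfg$k)
  rows <- list()
  values <- if (cfg$keep_values) list() else NULL
  for (ni in seq_along(cfg$n_grid)) {
    n <- cfg$n_grid[ni]
    vals <- matrix(NA_real_, cfg$k, length(fitters),
                   dimnames = list(NULL, names(fitters)))
    for (r in seq_len(cfg$k)) {
      smp <- sample_generator(cfg$generator, n, seed = seed_mat[r, ni])
      base_kl <- 0
      if (!gaussian && cfg$metric == "regret_vs_oracle") {
        base_kl <- kl_discrete(p_true, natural_oracle(p_true, smp),
                               unit = cfg$unit)
      }
      for (nm in names(fitters)) {
        v <- tryCatch({
          if (gaussian) {
            q <- fitters[[nm]](smp, n)
            kl_gaussian_divergence(p_true, q, scheme, cfg$unit)
          } else {
            kl_discrete(p_true, fitters[[nm]](smp), unit = cfg$unit)
          }
        }, error = function(e) NA_real_)
        vals[r, nm] <- if (is.na(v)) NA_real_ else v - base_kl
      }
    }
    for (nm in names(fitters)) {
      v <- vals[, nm]
      fin <- is.finite(v)
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = nm, n = n,
        mean = if (any(fin)) mean(v[fin]) else NA_real_,
        variance = if (sum(fin) > 1) stats::var(v[fin]) else NA_real_,
        worst_case = if (any(fin)) max(v[fin]) else NA_real_,
        worst_index = if (any(fin)) which(v == max(v[fin]))[1] else NA_integer_,
        infinite_count = sum(is.infinite(v)),
        excluded = sum(is.na(v)))
    }
    if (cfg$keep_values) values[[as.character(n)]] <- vals
  }
  structure(list(summary = do.call(rbind, rows), config = cfg,
                 values = values, seeds = seed_mat),
            class = "experiment_report")
}

## closed-form shortcut for Gaussian-vs-Gaussian; quadrature otherwise
kl_gaussian_divergence <- function(p, q, scheme, unit) {
  if (identical(q$kind, "gaussian")) {
    dm <- q$model$mean - p$mean
    ## equal known covariance: half the squared Mahalanobis distance
    return(to_unit(0.5 * drop(t(dm) %*% solve(p$cov, dm)), unit))
  }
  kl_gaussian_vs_density(p, q, scheme, unit)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report (", x$config$metric, ", ", x$config$unit, "), k = ",
      x$config$k, ", master seed ", x$config$master_seed, "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize an experiment report to JSON
#' @param report An \code{"experiment_report"}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  cfg <- report$config
  obj <- list(metric = cfg$metric, unit = cfg$unit, k = cfg$k,
              alpha = cfg$alpha, master_seed = cfg$master_seed,
              generator = cfg$generator[c("family", "m", "s")],
              summary = report$summary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "string")
  invisible(path)
}

#' Load an experiment configuration from a YAML file
#'
#' Expected keys: \code{generator} (family, m, s / mean, cov, seed),
#' \code{n_grid}, \code{k}, \code{estimators}, and optionally \code{alpha},
#' \code{metric}, \code{unit}, \code{master_seed}, \code{loo_base}.
#'
#' @param path YAML file path.
#' @return An \code{"experiment_config"}.
#' @export
load_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$generator
  gen <- if (identical(g$family, "gaussian")) {
    generator_spec("gaussian", mean = unlist(g$mean),
                   cov = if (is.null(g$cov)) NULL
                         else matrix(unlist(g$cov), nrow = length(unlist(g$mean))),
                   seed = g$seed %||% 1L)
  } else {
    generator_spec(g$family, m = g$m, s = g$s, seed = g$seed %||% 1L)
  }
  experiment_config(gen, n_grid = unlist(y$n_grid), k = y$k,
                    estimators = unlist(y$estimators),
                    alpha = y$alpha %||% 0.05, metric = y$metric %||% "kl",
                    unit = y$unit %||% "bits",
                    master_seed = y$master_seed %||% 1L,
                    loo_base = y$loo_base %||% "good_turing")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
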