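# shared fixtures, built in code

random_discrete <- function(m, seed) {
  set.seed(seed)
  w <- stats::runif(m)
  discrete_distribution(w / sum(w))
}

random_discrete_class <- function(n_models, m, seed) {
  set.seed(seed)
  finite_model_class(lapply(seq_len(n_models), function(i) {
    w <- stats::runif(m)
    discrete_distribution(w / sum(w))
  }))
}

# exhaustive grid-search oracle for capacity over a 2-simplex of priors:
# maximize I(pi) = sum_j pi_j D(p_j || q_pi) over the prior grid (step h)
capacity_grid_oracle <- function(class, h = 1e-3, offsets = NULL) {
  P <- do.call(rbind, lapply(class$models, `[[`, "probs"))
  stopifnot(nrow(P) == 3)
  w1 <- seq(0, 1, by = h)
  best <- -Inf
  off <- if (is.null(offsets)) numeric(3) else offsets
  logP <- log(P); logP[P == 0] <- 0
  rowneg <- rowSums(P * logP)
  for (a in w1) {
    b <- seq(0, 1 - a, by = h)
    pri <- cbind(a, b, 1 - a - b)
    Q <- pri %*% P
    lQ <- log(Q); lQ[Q == 0] <- 0
    ## D[i,j] = D(p_j || q_i); entries with pri = 0 never contribute to I
    D <- matrix(rowneg, nrow(pri), 3, byrow = TRUE) - tcrossprod(lQ, P)
    I <- rowSums(pri * sweep(D, 2, off))
    best <- max(best, max(I))
  }
  best / log(2)
}
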