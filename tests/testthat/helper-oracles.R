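# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks.

# O(B^2) double-loop construction of the Gaussian-weighted adjacency.
oracle_weights <- function(coords, delta) {
  B <- nrow(coords)
  W <- matrix(0, B, B)
  for (i in seq_len(B)) for (j in seq_len(B)) {
    if (i == j) next
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d < delta) W[i, j] <- exp(-d^2 / (2 * delta^2))
  }
  W
}

# Constrained minimizer of s' L s with s(K) fixed, solved through the full
# KKT (bordered) system in all B + |K| unknowns -- no K/U elimination.
oracle_interpolate_kkt <- function(known_idx, known_vals, L) {
  B <- nrow(L)
  k <- length(known_idx)
  C <- matrix(0, k, B)
  C[cbind(seq_len(k), known_idx)] <- 1
  A <- rbind(cbind(2 * L, t(C)),
             cbind(C, matrix(0, k, k)))
  sol <- solve(A, c(numeric(B), known_vals))
  unname(sol[seq_len(B)])
}

# Direct evaluation of the covariance-ratio correlation between two
# feature vectors.
oracle_pearson <- function(x, y) {
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

oracle_pearson_sc <- function(X) {
  B <- nrow(X)
  R <- diag(B)
  for (i in seq_len(B)) for (j in seq_len(B)) {
    if (i != j) R[i, j] <- oracle_pearson(X[i, ], X[j, ])
  }
  R
}

# Brute-force loop versions of the three connectome filters.
oracle_e2e <- function(X, c1, c2) {
  D <- nrow(X)
  out <- matrix(0, D, D)
  for (i in seq_len(D)) for (j in seq_len(D)) {
    out[i, j] <- sum(c1 * X[i, ]) + sum(c2 * X[, j])
  }
  out
}

oracle_e2n <- function(X, c1) {
  vapply(seq_len(nrow(X)), function(i) sum(c1 * X[i, ]), numeric(1))
}

oracle_n2g <- function(v, c2) {
  acc <- 0
  for (k in seq_along(v)) acc <- acc + c2[k] * v[k]
  acc
}

# Extrema by direct application of the strict-neighborhood definition on
# the weight matrix.
oracle_extrema <- function(x, W) {
  B <- length(x)
  minima <- integer(0)
  maxima <- integer(0)
  for (n in seq_len(B)) {
    nb <- which(W[n, ] > 0)
    if (length(nb) == 0) next
    if (all(x[n] > x[nb])) maxima <- c(maxima, n)
    if (all(x[n] < x[nb])) minima <- c(minima, n)
  }
  list(minima = minima, maxima = maxima)
}

# A small standard cohort used by augmentation/connectivity/classifier
# tests: B regions, 7 features, two groups.
toy_cohort <- function(B = 20, n_per_group = 6, seed = 42, effect = 1,
                       noise = 0.3, graph = NULL) {
  if (is.null(graph))
    graph <- suppressWarnings(
      make_toy_graph("geometric", B, delta = 0.9, seed = seed))
  spec <- synth_spec(B = B, n_gifted = n_per_group, n_control = n_per_group,
                     effect_size = effect, noise_sd = noise,
                     smoothness = min(6, B - 1), seed = seed)
  list(cohort = make_synthetic_cohort(spec, graph), graph = graph)
}
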