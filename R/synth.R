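#' Specification for a synthetic two-group cohort
#'
#' Collects the knobs of the synthetic cohort generator: cohort size
#' mirrors the study design it emulates (two groups of 15 and 14 male
#' children), signals are smooth over the region graph, and the group
#' difference is planted in the coupling between two morphometric features
#' inside a designated region block rather than in mean levels, because the
#' downstream structural-connectivity pipeline is correlation-based and
#' mean shifts would be absorbed by feature normalization.
#'
#' @param B number of regions (default 60; use 308 for full-scale shape
#'   checks).
#' @param F number of morphometric features (default 7).
#' @param n_gifted,n_control group sizes (defaults 15 and 14).
#' @param effect_size magnitude of the planted group difference in the
#'   cross-feature coupling (>= 0; 0 makes the groups exchangeable).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param smoothness number of lowest-frequency Laplacian eigenvectors
#'   composing the smooth base signal (must be < B).
#' @param block_regions indices of the region block carrying the planted
#'   effect; default: the first \code{ceiling(B/4)} regions.
#' @param seed RNG seed.
#' @return list of class \code{synth_spec}.
#' @export
synth_spec <- function(B = 60L, F = 7L, n_gifted = 15L, n_control = 14L,
                       effect_size = 1.0, noise_sd = 0.3, smoothness = 8L,
                       block_regions = NULL, seed = 1L) {
  if (B < 4L || F < 2L || n_gifted < 1L || n_control < 1L)
    stop("sizes too small")
  if (effect_size < 0) stop("'effect_size' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (smoothness >= B) stop("'smoothness' must be smaller than B")
  if (is.null(block_regions)) block_regions <- seq_len(ceiling(B / 4))
  structure(list(B = as.integer(B), F = as.integer(F),
                 n_gifted = as.integer(n_gifted),
                 n_control = as.integer(n_control),
                 effect_size = effect_size, noise_sd = noise_sd,
                 smoothness = as.integer(smoothness),
                 block_regions = as.integer(block_regions),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Synthetic brain-region centroid cloud
#'
#' Places B points quasi-uniformly on an ellipsoidal shell with brain-like
#' semi-axes (85, 70, 60 mm) using a Fibonacci lattice plus a small seeded
#' radial jitter, giving a deterministic, collision-free centroid cloud.
#'
#' @param B number of regions.
#' @param seed RNG seed for the jitter.
#' @return B x 3 numeric matrix of coordinates in mm.
#' @export
make_region_coordinates <- function(B, seed = 1L) {
  stopifnot(B >= 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  i <- seq_len(B) - 0.5
  golden <- (1 + sqrt(5)) / 2
  theta <- acos(1 - 2 * i / B)
  phi <- 2 * pi * i / golden
  r <- 1 + stats::rnorm(B, sd = 0.02)
  cbind(x = 85 * r * sin(theta) * cos(phi),
        y = 70 * r * sin(theta) * sin(phi),
        z = 60 * r * cos(theta))
}

#' Canonical toy graphs
#'
#' Small graphs with known structure used as substrates for decomposition
#' tests: a path, a ring, a rectangular grid (all unit edge weights with
#' consistent synthetic coordinates), or a random geometric graph built
#' with \code{\link{build_region_graph}}.
#'
#' @param kind one of \code{"path"}, \code{"ring"}, \code{"grid"},
#'   \code{"geometric"}.
#' @param n number of nodes (for \code{"grid"}, rounded up to a near-square
#'   layout).
#' @param delta distance threshold for \code{"geometric"} (default 0.35 on
#'   the unit cube).
#' @param seed RNG seed for \code{"geometric"} node placement.
#' @return a \code{region_graph}.
#' @export
make_toy_graph <- function(kind = c("path", "ring", "grid", "geometric"),
                           n, delta = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 2L)
  if (kind == "geometric") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    coords <- matrix(stats::runif(3 * n), ncol = 3)
    if (is.null(delta)) delta <- 0.35
    return(build_region_graph(coords, delta = delta))
  }
  W <- matrix(0, n, n)
  if (kind == "path") {
    for (i in seq_len(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
    coords <- cbind(seq_len(n), 0, 0)
  } else if (kind == "ring") {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      W[i, j] <- W[j, i] <- 1
    }
    ang <- 2 * pi * seq_len(n) / n
    coords <- cbind(cos(ang), sin(ang), 0)
  } else { # grid
    nc <- ceiling(sqrt(n))
    nr <- ceiling(n / nc)
    pos <- expand.grid(row = seq_len(nr), col = seq_len(nc))[seq_len(n), ]
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a < b && abs(pos$row[a] - pos$row[b]) +
            abs(pos$col[a] - pos$col[b]) == 1)
        W[a, b] <- W[b, a] <- 1
    }
    coords <- cbind(pos$col, pos$row, 0)
  }
  new_region_graph(W, coords = coords, kind = kind)
}

#' Generate a synthetic two-group cohort over a region graph
#'
#' Each subject's regions x features matrix is a sum of four parts:
#' \itemize{
#'   \item a shared anatomical factor: one smooth random field over the
#'     graph (a combination of the \code{smoothness} lowest-frequency
#'     Laplacian eigenvectors) loading uniformly on every feature,
#'     emulating the strong common component of morphometric features
#'     (bigger regions are thicker, larger, more voluminous);
#'   \item feature-specific smooth fields at half the amplitude
#'     (independent smooth deviations per feature);
#'   \item the planted effect: a subject-level expression \eqn{a \sim
#'     N(1, 0.2)} of a fixed block pattern, loading on the features with a
#'     group-dependent pattern scaled by \code{effect_size} -- uniformly
#'     across all features in the gifted group (a size-like component that
#'     is neutral to inter-feature correlation) and as a feature-family
#'     contrast (+1 on the first \code{floor(F/2)} features, -1 on the
#'     rest; a shape-vs-size trade-off) in the control group. The two
#'     loading patterns have equal length, so every marginal feature
#'     variance matches across groups and the groups differ purely in the
#'     inter-feature covariance inside the block (for \code{F = 2} this
#'     reduces to coupling the feature pair with a group-dependent sign);
#'   \item i.i.d. Gaussian noise with sd \code{noise_sd}.
#' }
#' With \code{effect_size = 0} the two groups are exchangeable.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @param graph a \code{region_graph} with \code{spec$B} nodes.
#' @return a \code{\link{new_cohort}} with labels \code{"gifted"} /
#'   \code{"control"}.
#' @export
make_synthetic_cohort <- function(spec, graph) {
  stopifnot(inherits(spec, "synth_spec"), inherits(graph, "region_graph"))
  B <- spec$B
  if (n_regions(graph) != B) stop("graph size does not match spec$B")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  eig <- eigen(graph$laplacian, symmetric = TRUE)
  # columns are sorted by decreasing eigenvalue; the smooth ones are last
  basis <- eig$vectors[, seq(B, B - spec$smoothness + 1L), drop = FALSE]
  amp <- sqrt(B / spec$smoothness)  # unit per-region variance per field
  smooth_field <- function(n)
    amp * basis %*% matrix(stats::rnorm(spec$smoothness * n), ncol = n)

  load_gifted <- rep(1, spec$F)
  load_control <- rep(c(1, -1),
                      c(floor(spec$F / 2), spec$F - floor(spec$F / 2)))

  labels <- c(rep("gifted", spec$n_gifted), rep("control", spec$n_control))
  subjects <- vector("list", length(labels))
  for (p in seq_along(labels)) {
    w <- smooth_field(1L)                       # shared anatomical factor
    X <- w %*% rep(1, spec$F) + 0.5 * smooth_field(spec$F)
    a <- stats::rnorm(1, mean = 1, sd = 0.2)    # expression level
    cf <- if (labels[p] == "gifted") load_gifted else load_control
    X[spec$block_regions, ] <- X[spec$block_regions, ] +
      spec$effect_size * a *
        matrix(cf, length(spec$block_regions), spec$F, byrow = TRUE)
    X <- X + matrix(stats::rnorm(B * spec$F, sd = spec$noise_sd), ncol = spec$F)
    subjects[[p]] <- X
  }
  grp <- ave(seq_along(labels), labels, FUN = seq_along)
  new_cohort(subjects, labels,
             subject_ids = sprintf("%s_%02d", labels, grp),
             feature_names = sprintf("feat%d", seq_len(spec$F)))
}

# Save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
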