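#' Local extrema of a graph signal
#'
#' A node is a local maximum when its value is strictly larger than the
#' value at every neighbor, and a local minimum when strictly smaller.
#' Strict comparison means plateaus produce no extrema; isolated nodes are
#' excluded from both sets.
#'
#' @param signal numeric vector of length B, aligned with graph node order.
#' @param graph a \code{region_graph}.
#' @return list with integer vectors \code{minima} and \code{maxima}.
#' @export
find_extrema <- function(signal, graph) {
  stopifnot(inherits(graph, "region_graph"))
  B <- n_regions(graph)
  if (length(signal) != B)
    stop("signal length does not match graph size")
  is_min <- logical(B)
  is_max <- logical(B)
  adj <- graph$adjacency
  for (n in seq_len(B)) {
    nb <- adj[[n]]
    if (length(nb) == 0L) next
    xv <- signal[n]
    xm <- signal[nb]
    is_max[n] <- all(xv > xm)
    is_min[n] <- all(xv < xm)
  }
  list(minima = which(is_min), maxima = which(is_max))
}

#' Dirichlet interpolation of a partially known graph signal
#'
#' Extends values fixed on a known node set K to the whole graph by
#' minimizing the total graph variation \eqn{s' L s} subject to
#' \eqn{s(K) = x(K)}. The minimizer is harmonic at every unknown node
#' (\eqn{(Ls)(u) = 0}), obtained by solving the reduced linear system
#' \eqn{L_{UU} s_U = -L_{UK} s_K} per connected component.
#'
#' A component containing no known node has a singular subproblem; those
#' nodes are filled with the global mean of the known values and a warning
#' is issued.
#'
#' @param known_idx integer vector of known node indices (nonempty,
#'   duplicate-free).
#' @param known_vals numeric values at \code{known_idx}.
#' @param graph a \code{region_graph}.
#' @return numeric length-B interpolated signal.
#' @export
graph_interpolate <- function(known_idx, known_vals, graph) {
  stopifnot(inherits(graph, "region_graph"))
  B <- n_regions(graph)
  known_idx <- as.integer(known_idx)
  if (length(known_idx) == 0L) stop("known node set must be nonempty")
  if (anyDuplicated(known_idx)) stop("duplicate known node indices")
  if (any(known_idx < 1L | known_idx > B)) stop("known index out of range")
  if (length(known_vals) != length(known_idx))
    stop("known_vals length must match known_idx")
  s <- numeric(B)
  s[known_idx] <- known_vals
  known <- logical(B)
  known[known_idx] <- TRUE
  unknown <- which(!known)
  if (length(unknown) == 0L) return(s)

  # components with no anchor get the global mean of the known values
  comp_has_known <- tapply(known, graph$membership, any)
  orphan_comps <- as.integer(names(comp_has_known)[!comp_has_known])
  if (length(orphan_comps) > 0L) {
    orphan_nodes <- which(graph$membership %in% orphan_comps)
    s[orphan_nodes] <- mean(known_vals)
    warning(sprintf(
      "%d component(s) contain no known node; filled with the mean of known values",
      length(orphan_comps)))
    unknown <- setdiff(unknown, orphan_nodes)
    if (length(unknown) == 0L) return(s)
  }

  L <- graph$laplacian
  kset <- which(known)
  rhs <- -L[unknown, kset, drop = FALSE] %*% s[kset]
  s[unknown] <- solve(L[unknown, unknown, drop = FALSE], rhs)
  s
}

# TRUE when the signal has at least one minimum and one maximum, i.e. one
# more sifting step is well defined.
is_siftable <- function(signal, graph) {
  ext <- find_extrema(signal, graph)
  length(ext$minima) > 0L && length(ext$maxima) > 0L
}

#' Upper and lower envelopes of a graph signal
#'
#' Interpolates the signal values at its local maxima (upper envelope) and
#' local minima (lower envelope) over the whole graph via
#' \code{\link{graph_interpolate}}. Each envelope coincides with the signal
#' at its defining extrema.
#'
#' @inheritParams find_extrema
#' @return list with numeric vectors \code{e_min} and \code{e_max}.
#' @export
envelopes <- function(signal, graph) {
  ext <- find_extrema(signal, graph)
  if (length(ext$minima) == 0L || length(ext$maxima) == 0L)
    stop(structure(
      class = c("gemd_monotone", "error", "condition"),
      list(message = "signal has no extrema of one kind (trend over the graph)",
           call = sys.call())))
  list(e_min = graph_interpolate(ext$minima, signal[ext$minima], graph),
       e_max = graph_interpolate(ext$maxima, signal[ext$maxima], graph))
}

#' Mean envelope
#'
#' Elementwise average \code{(e_min + e_max) / 2} of the two envelopes.
#'
#' @param e_min,e_max numeric vectors of equal length.
#' @return numeric vector.
#' @export
mean_envelope <- function(e_min, e_max) {
  if (length(e_min) != length(e_max)) stop("envelope lengths differ")
  (e_min + e_max) / 2
}

#' Graph empirical mode decomposition
#'
#' Decomposes a graph signal into intrinsic mode functions (IMFs) by
#' iterated sifting. Each IMF is extracted by repeatedly subtracting the
#' mean envelope from the current working signal until the envelope energy
#' drops below the energy of the signal entering that extraction divided by
#' \code{energy_ratio} (or \code{max_sift_iters} is hit); extraction of new
#' IMFs stops when the residual has no extrema of one kind (a trend over
#' the graph) or \code{max_imfs} have been extracted. Energy is the sum of
#' squared node values.
#'
#' The extracted IMFs plus the residual always reconstruct the input
#' exactly up to floating point (a telescoping identity of the sifting
#' recursion).
#'
#' @inheritParams find_extrema
#' @param max_imfs maximum number of IMFs to extract; the IMF matrix is
#'   zero-padded to exactly this many rows.
#' @param energy_ratio sifting stops once \code{energy(mean envelope) <
#'   energy(signal) / energy_ratio} (default 1000).
#' @param max_sift_iters hard cap on sifting iterations per IMF.
#' @return An object of class \code{imf_stack}: list with \code{imfs}
#'   (\code{max_imfs} x B matrix, rows beyond \code{n_extracted} are zero),
#'   \code{residual} (length-B), \code{n_extracted}, and \code{max_imfs}.
#' @examples
#' g <- make_toy_graph("ring", 16)
#' x <- sin(seq(0, 4 * pi, length.out = 16)) + rnorm(16, sd = 0.1)
#' st <- gemd_decompose(x, g)
#' max(abs(colSums(st$imfs) + st$residual - x))  # ~ 0
#' @export
gemd_decompose <- function(signal, graph, max_imfs = 5L,
                           energy_ratio = 1000, max_sift_iters = 50L) {
  stopifnot(inherits(graph, "region_graph"))
  B <- n_regions(graph)
  if (length(signal) != B) stop("signal length does not match graph size")
  if (any(!is.finite(signal))) stop("signal must be finite")
  if (max_imfs < 1L) stop("'max_imfs' must be >= 1")
  if (energy_ratio <= 0) stop("'energy_ratio' must be positive")

  imfs <- matrix(0, nrow = max_imfs, ncol = B)
  x <- signal
  n_extracted <- 0L
  for (i in seq_len(max_imfs)) {
    e_x <- sum(x^2)
    if (e_x == 0 || !is_siftable(x, graph)) break
    m <- x
    for (it in seq_len(max_sift_iters)) {
      if (!is_siftable(m, graph)) break
      env <- envelopes(m, graph)
      z <- mean_envelope(env$e_min, env$e_max)
      m <- m - z
      if (sum(z^2) < e_x / energy_ratio) break
    }
    # a mode that lost its oscillation during sifting belongs to the trend:
    # leave its content in the residual and stop extracting
    if (!is_siftable(m, graph)) break
    imfs[i, ] <- m
    x <- x - m
    n_extracted <- i
  }
  structure(list(imfs = imfs, residual = x, n_extracted = n_extracted,
                 max_imfs = as.integer(max_imfs)),
            class = "imf_stack")
}

#' @export
print.imf_stack <- function(x, ...) {
  cat(sprintf("imf_stack: %d of %d IMF slot(s) extracted, B = %d\n",
              x$n_extracted, x$max_imfs, ncol(x$imfs)))
  invisible(x)
}

#' Decompose every feature of every subject in a cohort
#'
#' Runs \code{\link{gemd_decompose}} independently on each feature column
#' of each subject, producing the M x B x F x P IMF tensor used by the
#' recombination augmentation. Stacks are zero-padded to exactly \code{M}
#' slots (padding occupies the highest-index, low-frequency positions) and
#' each decomposition's residual is folded into slot \code{M}, so that
#' summing the tensor over its first axis reproduces the input cohort and
#' recombined artificial subjects conserve total signal content.
#'
#' @param cohort a \code{cohort} (see \code{\link{new_cohort}}).
#' @param graph a \code{region_graph} with B matching the cohort.
#' @param M number of IMF slots (default 5).
#' @param energy_ratio,max_sift_iters passed to \code{gemd_decompose}.
#' @return An \code{imf_tensor}: a numeric array of dim \code{c(M, B, F, P)}
#'   with attributes \code{subject_ids}, \code{labels}, \code{feature_names},
#'   \code{region_ids}, and \code{max_reconstruction_error}.
#' @export
decompose_cohort <- function(cohort, graph, M = 5L, energy_ratio = 1000,
                             max_sift_iters = 50L) {
  stopifnot(inherits(cohort, "cohort"), inherits(graph, "region_graph"))
  B <- cohort$B
  n_feat <- cohort$F
  P <- length(cohort$subjects)
  if (B != n_regions(graph))
    stop("cohort region count does not match graph size")
  tens <- array(0, dim = c(M, B, n_feat, P))
  worst <- 0
  for (p in seq_len(P)) {
    X <- cohort$subjects[[p]]
    for (f in seq_len(n_feat)) {
      st <- gemd_decompose(X[, f], graph, max_imfs = M,
                           energy_ratio = energy_ratio,
                           max_sift_iters = max_sift_iters)
      imfs <- st$imfs
      imfs[M, ] <- imfs[M, ] + st$residual   # fold residual into last slot
      tens[, , f, p] <- imfs
      worst <- max(worst, max(abs(colSums(imfs) - X[, f])) /
                     max(1, max(abs(X[, f]))))
    }
  }
  if (worst > 1e-8)
    warning(sprintf("cohort reconstruction error %.3g exceeds 1e-8", worst))
  structure(tens,
            subject_ids = cohort$subject_ids,
            labels = cohort$labels,
            feature_names = cohort$feature_names,
            region_ids = graph$region_ids,
            max_reconstruction_error = worst,
            class = c("imf_tensor", "array"))
}
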