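#' Build the weighted region graph
#'
#' Constructs the weighted, undirected graph over brain regions that all
#' decomposition operations run on. Two regions are joined by an edge when
#' their Euclidean distance is strictly smaller than the bandwidth
#' \code{delta}, with Gaussian weight \eqn{w_{ij} = \exp(-d_{ij}^2 / (2
#' \delta^2))}. The combinatorial Laplacian \eqn{L = D - W} is precomputed
#' along with the adjacency structure and connected components.
#'
#' The point matrix is typically the B x 3 table of region centroids in mm,
#' but any B x k coordinate matrix is accepted, so distances can also be
#' taken in a feature space by passing a feature matrix instead.
#'
#' @param coords numeric matrix, one row per region (columns are spatial or
#'   feature coordinates; all entries must be finite).
#' @param delta positive distance threshold / Gaussian bandwidth, in the
#'   units of \code{coords}. When \code{NULL} (default) it is set to the
#'   30th percentile of the pairwise distances.
#' @param region_ids optional character vector of region identifiers;
#'   defaults to rownames of \code{coords} or \code{"R001"}-style labels.
#' @return An object of class \code{region_graph}: a list with elements
#'   \code{region_ids}, \code{coords}, \code{delta}, \code{weights} (B x B
#'   symmetric, zero diagonal, entries in \[0, 1\]), \code{laplacian},
#'   \code{adjacency} (list of neighbor index vectors), \code{membership}
#'   (component id per node) and \code{n_components}.
#' @examples
#' coords <- matrix(rnorm(30), ncol = 3)
#' g <- build_region_graph(coords, delta = 2)
#' g$n_components
#' @export
build_region_graph <- function(coords, delta = NULL, region_ids = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || any(!is.finite(coords)))
    stop("'coords' must be a numeric matrix with finite entries")
  B <- nrow(coords)
  if (B < 2L) stop("need at least 2 regions")
  dmat <- as.matrix(stats::dist(coords))
  if (is.null(delta)) {
    delta <- stats::quantile(dmat[upper.tri(dmat)], 0.30, names = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0)
    stop("'delta' must be a single positive number")
  W <- exp(-dmat^2 / (2 * delta^2))
  W[dmat >= delta] <- 0           # strict threshold: d == delta drops the edge
  diag(W) <- 0
  if (is.null(region_ids)) {
    region_ids <- rownames(coords)
    if (is.null(region_ids))
      region_ids <- sprintf("R%03d", seq_len(B))
  }
  if (length(region_ids) != B) stop("'region_ids' must have one id per region")
  new_region_graph(W, coords = coords, delta = delta,
                   region_ids = as.character(region_ids))
}

# Internal constructor shared by build_region_graph and the toy-graph
# factory; W must already be symmetric, nonnegative, zero-diagonal.
new_region_graph <- function(W, coords = NULL, delta = NA_real_,
                             region_ids = NULL, kind = "geometric") {
  B <- nrow(W)
  if (is.null(region_ids)) region_ids <- sprintf("R%03d", seq_len(B))
  dimnames(W) <- list(region_ids, region_ids)
  L <- diag(rowSums(W), nrow = B) - W
  adjacency <- lapply(seq_len(B), function(i) which(W[i, ] > 0))
  ig <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
  comp <- igraph::components(ig)
  if (comp$no > 1L)
    warning(sprintf("region graph is disconnected (%d components)", comp$no))
  structure(
    list(region_ids = region_ids, coords = coords, delta = delta,
         weights = W, laplacian = L, adjacency = adjacency,
         membership = as.integer(comp$membership),
         n_components = comp$no, kind = kind),
    class = "region_graph")
}

#' Number of nodes in a region graph
#' @param graph a \code{region_graph}.
#' @return integer node count.
#' @export
n_regions <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  nrow(graph$weights)
}

#' Neighbors of a node
#'
#' Indices of the nodes sharing an edge (positive weight) with \code{node}.
#' The node itself is never included; an isolated node returns an empty set.
#'
#' @param graph a \code{region_graph}.
#' @param node single node index in \code{1..B}.
#' @return integer vector of neighbor indices.
#' @export
neighbors <- function(graph, node) {
  stopifnot(inherits(graph, "region_graph"))
  B <- n_regions(graph)
  if (length(node) != 1L || is.na(node) || node < 1L || node > B)
    stop("'node' index out of range")
  graph$adjacency[[node]]
}

#' @export
print.region_graph <- function(x, ...) {
  n_edges <- sum(x$weights > 0) / 2
  cat(sprintf("region_graph: %d nodes, %d edges, %d component(s)\n",
              n_regions(x), n_edges, x$n_components))
  if (is.finite(x$delta))
    cat(sprintf("  delta = %.4g, kind = %s\n", x$delta, x$kind))
  invisible(x)
}

#' Export a region graph as an edge list
#'
#' Writes a three-column TSV (\code{i}, \code{j}, \code{weight}) of the
#' upper-triangular edges, using region ids.
#'
#' @param graph a \code{region_graph}.
#' @param path output file path.
#' @return the edge-list data frame, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "region_graph"))
  W <- graph$weights
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  el <- data.frame(i = graph$region_ids[idx[, 1]],
                   j = graph$region_ids[idx[, 2]],
                   weight = W[idx])
  utils::write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(el)
}
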