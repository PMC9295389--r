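#' Standardize feature columns across regions
#'
#' Morphometric features live on incommensurate scales (mm^3 volumes vs
#' dimensionless curvature indices), so each feature column is z-scored
#' across regions (population standard deviation) before regions are
#' correlated. Constant columns become zero with a warning.
#'
#' @param subject B x F numeric matrix.
#' @return B x F matrix with column means 0 and population variance 1.
#' @export
normalize_features <- function(subject) {
  X <- as.matrix(subject)
  if (ncol(X) == 0L) stop("subject has no feature columns")
  if (nrow(X) < 3L) stop("need at least 3 regions")
  B <- nrow(X)
  mu <- colMeans(X)
  sdp <- sqrt(colMeans(X^2) - mu^2)  # population sd
  out <- sweep(X, 2, mu)
  const <- sdp < .Machine$double.eps^0.5
  if (any(const)) {
    warning(sprintf("%d constant feature column(s) set to zero", sum(const)))
    sdp[const] <- 1
    out[, const] <- 0
  }
  sweep(out, 2, sdp, "/")
}

#' Per-subject structural connectivity (morphometric similarity)
#'
#' Correlates the F morphometric values of every region with those of every
#' other region, giving a single subject's B x B structural-connectivity
#' matrix: \eqn{c(x, y) = S_{xy} / \sqrt{S_{xx} S_{yy}}} with
#' \eqn{S_{xy} = \sum_i (x_i - \bar x)(y_i - \bar y)} over the F paired
#' feature values. This is the single-subject inter-regional correlation of
#' multiple MRI features, as opposed to across-subject structural
#' covariance of one feature.
#'
#' @param subject B x F numeric matrix (F >= 2).
#' @param normalize z-score feature columns first
#'   (\code{\link{normalize_features}}; default \code{TRUE}).
#' @param subject_id optional id stored on the result.
#' @return an \code{sc_matrix}: list with \code{values} (B x B, symmetric,
#'   unit diagonal), \code{standardized = FALSE}, \code{subject_id}.
#' @export
pearson_sc <- function(subject, normalize = TRUE, subject_id = NA_character_) {
  X <- as.matrix(subject)
  if (ncol(X) < 2L) stop("need at least 2 features to correlate regions")
  if (normalize) X <- normalize_features(X)
  rv <- apply(X, 1, stats::var)
  R <- suppressWarnings(stats::cor(t(X)))
  zero <- rv < .Machine$double.eps
  if (any(zero)) {
    warning(sprintf(
      "%d region(s) have zero variance across features; correlations set to 0",
      sum(zero)))
    R[zero, ] <- 0
    R[, zero] <- 0
  }
  R[is.na(R)] <- 0
  diag(R) <- 1
  R <- (R + t(R)) / 2
  structure(list(values = R, standardized = FALSE, subject_id = subject_id),
            class = "sc_matrix")
}

#' Standardize a structural-connectivity matrix
#'
#' Z-scores the off-diagonal entries within the subject (subtract their
#' mean, divide by their population standard deviation) and sets the
#' diagonal to zero; self-connections carry no information for the
#' classifier. Re-applying the operation is idempotent. A Fisher r-to-z
#' variant and a pass-through are available for comparison.
#'
#' @param sc an \code{sc_matrix} (from \code{\link{pearson_sc}}).
#' @param method \code{"zscore"} (default), \code{"fisher"}, or
#'   \code{"none"}.
#' @return an \code{sc_matrix} with \code{standardized = TRUE} (for
#'   \code{"zscore"}/\code{"fisher"}).
#' @export
zscore_sc <- function(sc, method = c("zscore", "fisher", "none")) {
  stopifnot(inherits(sc, "sc_matrix"))
  method <- match.arg(method)
  V <- sc$values
  if (method == "none") return(sc)
  off <- !diag(nrow(V))
  vals <- V[off]
  if (method == "fisher") {
    vals <- atanh(pmin(pmax(vals, -1 + 1e-7), 1 - 1e-7))
    V[off] <- vals
    diag(V) <- 0
  } else {
    sdp <- sqrt(mean(vals^2) - mean(vals)^2)  # population sd
    if (sdp < .Machine$double.eps^0.5)
      stop("degenerate SC: off-diagonal entries have zero variance")
    V[off] <- (vals - mean(vals)) / sdp
    diag(V) <- 0
  }
  structure(list(values = V, standardized = TRUE,
                 subject_id = sc$subject_id),
            class = "sc_matrix")
}

#' @export
print.sc_matrix <- function(x, ...) {
  cat(sprintf("sc_matrix: %d x %d, %s\n", nrow(x$values), ncol(x$values),
              if (x$standardized) "standardized" else "raw correlations"))
  invisible(x)
}

#' Structural-connectivity tensor for a cohort
#'
#' Stacks the per-subject standardized SC matrices into a P x B x B array
#' aligned with the cohort's subject order and labels.
#'
#' @param cohort a \code{cohort}.
#' @param normalize passed to \code{\link{pearson_sc}}.
#' @param standardize passed to \code{\link{zscore_sc}} as \code{method}.
#' @return numeric array of dim \code{c(P, B, B)} with attributes
#'   \code{subject_ids} and \code{labels}.
#' @export
cohort_sc <- function(cohort, normalize = TRUE,
                      standardize = c("zscore", "fisher", "none")) {
  stopifnot(inherits(cohort, "cohort"))
  standardize <- match.arg(standardize)
  P <- length(cohort$subjects)
  out <- array(0, dim = c(P, cohort$B, cohort$B))
  for (p in seq_len(P)) {
    sc <- pearson_sc(cohort$subjects[[p]], normalize = normalize,
                     subject_id = cohort$subject_ids[p])
    sc <- zscore_sc(sc, method = standardize)
    out[p, , ] <- sc$values
  }
  structure(out, subject_ids = cohort$subject_ids, labels = cohort$labels)
}

#' Write one subject's SC matrix to CSV
#'
#' @param sc an \code{sc_matrix}.
#' @param path output CSV path.
#' @param region_ids optional row/column labels.
#' @return the file path, invisibly.
#' @export
write_sc_matrix <- function(sc, path, region_ids = NULL) {
  stopifnot(inherits(sc, "sc_matrix"))
  V <- sc$values
  if (!is.null(region_ids)) dimnames(V) <- list(region_ids, region_ids)
  utils::write.csv(V, path, row.names = !is.null(region_ids))
  invisible(path)
}
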