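#' Recombine one artificial subject from M donors
#'
#' Builds an artificial feature matrix by summing one intrinsic mode
#' function from each of M donor subjects of the same group: donor m
#' contributes the IMF in slot \code{perm[m]}, so every slot (frequency
#' band) is represented exactly once. The same donors and slot assignment
#' are used for all features, preserving within-subject cross-feature
#' coupling.
#'
#' @param imf_tensor M x B x F x P array of IMFs for the donor pool (one
#'   group), as produced by \code{\link{decompose_cohort}} (residuals
#'   folded into the last slot).
#' @param donor_indices integer vector of exactly M subject indices into
#'   the pool's fourth axis; must be distinct unless \code{replace = TRUE}.
#' @param perm permutation of \code{1:M} assigning IMF slots to donors;
#'   \code{NULL} draws one uniformly from the current RNG stream.
#' @param replace allow repeated donors (used by the degenerate
#'   single-donor reconstruction identity).
#' @return B x F numeric matrix.
#' @export
make_artificial_sample <- function(imf_tensor, donor_indices, perm = NULL,
                                   replace = FALSE) {
  d <- dim(imf_tensor)
  if (length(d) != 4L) stop("'imf_tensor' must be an M x B x F x P array")
  M <- d[1]
  if (length(donor_indices) != M)
    stop(sprintf("need exactly %d donors (one per IMF slot)", M))
  if (!replace && anyDuplicated(donor_indices))
    stop("donors must be distinct (set replace = TRUE to allow repeats)")
  if (any(donor_indices < 1L | donor_indices > d[4]))
    stop("donor index out of range")
  if (is.null(perm)) perm <- sample.int(M)
  if (!identical(sort(as.integer(perm)), seq_len(M)))
    stop("'perm' must be a permutation of 1:M")
  out <- matrix(0, d[2], d[3])
  for (m in seq_len(M))
    out <- out + imf_tensor[perm[m], , , donor_indices[m]]
  out
}

#' Augment a training cohort with GEMD-recombined artificial subjects
#'
#' Generates \code{n_per_group} artificial subjects per group by sampling,
#' for each artificial subject, M distinct donors from that group and a
#' uniform slot permutation, then summing the assigned IMFs
#' (\code{\link{make_artificial_sample}}). Artificial subjects carry their
#' donor ids and slot permutation as provenance and are labelled with the
#' donor group. The result is reproducible given \code{seed}: a single
#' seeded RNG stream is consumed sequentially across samples.
#'
#' @param train a training \code{cohort} (original subjects only).
#' @param imfs an \code{imf_tensor} from \code{\link{decompose_cohort}} run
#'   on \code{train} (subject axis aligned with \code{train}).
#' @param n_per_group number of artificial subjects per group (>= 0).
#' @param seed RNG seed.
#' @param replace allow donor repetition within one artificial sample
#'   (needed when a group has fewer than M subjects).
#' @param per_feature_donors if \code{TRUE}, donors and permutation are
#'   re-drawn independently for every feature column (breaks cross-feature
#'   coupling; default \code{FALSE}).
#' @return the augmented \code{cohort}: original subjects first, then the
#'   artificial ones.
#' @export
augment_training_set <- function(train, imfs, n_per_group, seed = 1L,
                                 replace = FALSE, per_feature_donors = FALSE) {
  stopifnot(inherits(train, "cohort"))
  d <- dim(imfs)
  if (length(d) != 4L || d[4] != length(train$subjects))
    stop("'imfs' does not match the training cohort")
  if (n_per_group < 0L) stop("'n_per_group' must be >= 0")
  if (n_per_group == 0L) return(train)
  M <- d[1]
  groups <- sort(unique(train$labels))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  subjects <- train$subjects
  labels <- train$labels
  ids <- train$subject_ids
  prov <- train$provenance
  for (g in groups) {
    pool <- which(train$labels == g)
    if (!replace && length(pool) < M)
      stop(sprintf(
        "group '%s' has %d subjects but %d donors are needed; reduce M or set replace = TRUE",
        g, length(pool), M))
    for (k in seq_len(n_per_group)) {
      if (per_feature_donors) {
        X <- matrix(0, train$B, train$F)
        donor_rec <- vector("list", train$F)
        for (f in seq_len(train$F)) {
          donors <- sample(pool, M, replace = replace)
          perm <- sample.int(M)
          for (m in seq_len(M))
            X[, f] <- X[, f] + imfs[perm[m], , f, donors[m]]
          donor_rec[[f]] <- list(donors = train$subject_ids[donors],
                                 perm = perm)
        }
        prov_entry <- list(donors = donor_rec, per_feature = TRUE)
      } else {
        donors <- sample(pool, M, replace = replace)
        perm <- sample.int(M)
        X <- make_artificial_sample(imfs, donors, perm = perm,
                                    replace = replace)
        prov_entry <- list(donors = train$subject_ids[donors], perm = perm)
      }
      subjects <- c(subjects, list(X))
      labels <- c(labels, g)
      ids <- c(ids, sprintf("art_%s_%03d", g, k))
      prov <- c(prov, list(prov_entry))
    }
  }
  new_cohort(subjects, labels, ids, train$feature_names, prov)
}

#' SMOTE oversampling of flattened feature vectors
#'
#' Classic synthetic-minority oversampling: each synthetic row is
#' \eqn{x + u (x_{nn} - x)} for a random base sample x, a random one of its
#' k nearest same-group neighbors (Euclidean), and \eqn{u \sim U(0, 1)}.
#'
#' @param group_features P x q numeric matrix (one flattened subject per
#'   row; all from one group).
#' @param n number of synthetic rows to generate.
#' @param k neighborhood size (must satisfy \code{k < P}).
#' @param seed RNG seed.
#' @return n x q numeric matrix.
#' @export
smote_sample <- function(group_features, n, k = 5L, seed = 1L) {
  X <- as.matrix(group_features)
  P <- nrow(X)
  if (P < 2L) stop("need at least 2 samples")
  if (k >= P) stop("'k' must be smaller than the number of samples")
  if (n < 0L) stop("'n' must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- matrix(0L, P, k)
  for (i in seq_len(P)) nn[i, ] <- order(D[i, ])[seq_len(k)]
  out <- matrix(0, n, ncol(X))
  for (i in seq_len(n)) {
    base <- sample.int(P, 1)
    nbr <- nn[base, sample.int(k, 1)]
    u <- stats::runif(1)
    out[i, ] <- X[base, ] + u * (X[nbr, ] - X[base, ])
  }
  out
}

#' SMOTE-augment a training cohort
#'
#' Applies \code{\link{smote_sample}} per group to the flattened feature
#' matrices and unflattens the synthetic rows back into B x F subjects, so
#' the baseline acts at the same pipeline stage as the GEMD recombination.
#'
#' @inheritParams augment_training_set
#' @param k SMOTE neighborhood size.
#' @return the augmented \code{cohort}.
#' @export
augment_training_set_smote <- function(train, n_per_group, k = 5L, seed = 1L) {
  stopifnot(inherits(train, "cohort"))
  if (n_per_group < 0L) stop("'n_per_group' must be >= 0")
  if (n_per_group == 0L) return(train)
  subjects <- train$subjects
  labels <- train$labels
  ids <- train$subject_ids
  prov <- train$provenance
  for (g in sort(unique(train$labels))) {
    pool <- which(train$labels == g)
    flat <- flatten_cohort(cohort_subset(train, pool))
    kg <- min(k, length(pool) - 1L)
    syn <- smote_sample(flat, n = n_per_group, k = kg,
                        seed = seed + match(g, sort(unique(train$labels))))
    for (i in seq_len(n_per_group)) {
      subjects <- c(subjects, list(matrix(syn[i, ], train$B, train$F)))
      labels <- c(labels, g)
      ids <- c(ids, sprintf("smote_%s_%03d", g, i))
      prov <- c(prov, list(list(donors = train$subject_ids[pool],
                                method = "smote")))
    }
  }
  new_cohort(subjects, labels, ids, train$feature_names, prov)
}
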