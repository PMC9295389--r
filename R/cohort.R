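#' Construct a labelled cohort of subjects
#'
#' A cohort bundles per-subject regions x features matrices with group
#' labels, subject ids and provenance (whether a subject is an original
#' measurement or an artificial recombination, and if artificial, which
#' donors produced it).
#'
#' @param subjects list of B x F numeric matrices, one per subject, all
#'   with identical dimensions.
#' @param labels character/factor of group labels, one per subject; exactly
#'   two distinct groups are expected downstream.
#' @param subject_ids optional character ids (default \code{"S001"} style).
#' @param feature_names optional length-F character vector.
#' @param provenance optional list, one entry per subject: either the
#'   string \code{"original"} or a list with elements \code{donors}
#'   (character donor ids) and \code{perm} (IMF slot permutation).
#' @return object of class \code{cohort}.
#' @export
new_cohort <- function(subjects, labels, subject_ids = NULL,
                       feature_names = NULL, provenance = NULL) {
  if (!is.list(subjects) || length(subjects) == 0L)
    stop("'subjects' must be a nonempty list of matrices")
  dims <- vapply(subjects, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all subjects must share the same B x F dimensions")
  P <- length(subjects)
  labels <- as.character(labels)
  if (length(labels) != P) stop("one label per subject required")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(P))
  if (length(subject_ids) != P) stop("one subject id per subject required")
  if (anyDuplicated(subject_ids)) stop("subject ids must be unique")
  if (is.null(feature_names)) feature_names <- sprintf("f%d", seq_len(dims[2, 1]))
  if (is.null(provenance)) provenance <- rep(list("original"), P)
  subjects <- lapply(subjects, function(m) {
    m <- as.matrix(m)
    dimnames(m) <- NULL
    m
  })
  structure(list(subjects = subjects, labels = labels,
                 subject_ids = as.character(subject_ids),
                 feature_names = as.character(feature_names),
                 provenance = provenance,
                 B = dims[1, 1], F = dims[2, 1]),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$labels)
  art <- sum(!vapply(x$provenance, identical, logical(1), "original"))
  cat(sprintf("cohort: %d subject(s) (%s), B = %d regions, F = %d features",
              length(x$subjects),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$B, x$F))
  if (art > 0) cat(sprintf(", %d artificial", art))
  cat("\n")
  invisible(x)
}

#' Subset a cohort by subject index
#' @param cohort a \code{cohort}.
#' @param idx integer or logical subject index.
#' @return a \code{cohort} containing the selected subjects.
#' @export
cohort_subset <- function(cohort, idx) {
  stopifnot(inherits(cohort, "cohort"))
  new_cohort(cohort$subjects[idx], cohort$labels[idx],
             cohort$subject_ids[idx], cohort$feature_names,
             cohort$provenance[idx])
}

#' Flatten a cohort to a subjects x (B*F) matrix
#'
#' Concatenates each subject's feature matrix column-wise into a single row
#' vector; 308 regions x 7 features yield 2156 values per subject. This is
#' the representation used by the SMOTE baseline and by simple vector
#' classifiers.
#'
#' @param cohort a \code{cohort}.
#' @return P x (B*F) numeric matrix with subject ids as row names.
#' @export
flatten_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  out <- t(vapply(cohort$subjects, as.vector,
                  numeric(cohort$B * cohort$F)))
  rownames(out) <- cohort$subject_ids
  out
}
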