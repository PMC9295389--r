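#' Split a cohort into training and test sets
#'
#' The fixed-split protocol draws \code{n_train_per_group} subjects per
#' group (default 7 + 7 = 14) into the training set and keeps the remaining
#' subjects as the test set. The k-fold protocol returns stratified fold
#' assignments instead.
#'
#' @param cohort a \code{cohort} of original subjects.
#' @param split_spec list: either \code{list(type = "fixed",
#'   n_train_per_group = 7)} or \code{list(type = "kfold", k = 10)}.
#' @param seed seed for the random draw.
#' @return for \code{"fixed"}: list with integer vectors \code{train} and
#'   \code{test}; for \code{"kfold"}: list with \code{folds}, an integer
#'   fold id per subject.
#' @export
split_cohort <- function(cohort, split_spec = list(type = "fixed",
                                                   n_train_per_group = 7L),
                         seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  groups <- sort(unique(cohort$labels))
  if (identical(split_spec$type, "kfold")) {
    k <- split_spec$k %||% 10L
    folds <- integer(length(cohort$labels))
    for (g in groups) {
      idx <- sample(which(cohort$labels == g))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    return(list(folds = folds, k = k))
  }
  ntr <- split_spec$n_train_per_group %||% 7L
  train <- integer(0)
  for (g in groups) {
    pool <- which(cohort$labels == g)
    if (length(pool) <= ntr)
      stop(sprintf("group '%s' too small for %d training subjects + a test set",
                   g, ntr))
    train <- c(train, sample(pool, ntr))
  }
  list(train = sort(train), test = setdiff(seq_along(cohort$labels), train))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one train/augment/evaluate session
#'
#' Implements the augmentation experiment protocol: split the original
#' cohort, augment the training split only (test subjects never donate
#' IMFs), compute structural connectivity for both splits, train the
#' classifier on the (augmented) training SC tensor, and evaluate on the
#' held-out test subjects. A leakage guard verifies that every donor id in
#' the artificial subjects' provenance belongs to the training split and
#' aborts otherwise.
#'
#' @param cohort original \code{cohort}.
#' @param graph the \code{region_graph} the cohort lives on.
#' @param n_artificial artificial subjects per group.
#' @param method \code{"gemd"}, \code{"smote"}, or \code{"none"}.
#' @param seed session seed (drives the split, augmentation and training).
#' @param split_spec see \code{\link{split_cohort}} (fixed split only).
#' @param config optional \code{\link{brainnet_config}}; defaults to the
#'   standard architecture at the cohort's region count.
#' @param M IMF slots for GEMD augmentation.
#' @param smote_k SMOTE neighborhood size.
#' @param imfs optional precomputed \code{\link{decompose_cohort}} tensor
#'   for the FULL cohort (subject axis aligned); the training-split slices
#'   are extracted from it, saving repeated decomposition across sessions.
#' @return one-row data frame: \code{method}, \code{n_artificial},
#'   \code{seed}, \code{n_train}, \code{n_test}, \code{accuracy}, and
#'   \code{final_train_loss}.
#' @export
run_session <- function(cohort, graph, n_artificial = 0L,
                        method = c("none", "gemd", "smote"), seed = 1L,
                        split_spec = list(type = "fixed",
                                          n_train_per_group = 7L),
                        config = NULL, M = 5L, smote_k = 5L, imfs = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "cohort"), inherits(graph, "region_graph"))
  sp <- split_cohort(cohort, split_spec, seed = seed)
  train <- cohort_subset(cohort, sp$train)
  test <- cohort_subset(cohort, sp$test)

  if (n_artificial > 0L && method == "gemd") {
    tens <- if (is.null(imfs)) {
      decompose_cohort(train, graph, M = M)
    } else {
      structure(imfs[, , , sp$train, drop = FALSE],
                subject_ids = cohort$subject_ids[sp$train],
                class = c("imf_tensor", "array"))
    }
    train_aug <- augment_training_set(train, tens, n_per_group = n_artificial,
                                      seed = seed + 1000L)
  } else if (n_artificial > 0L && method == "smote") {
    train_aug <- augment_training_set_smote(train, n_per_group = n_artificial,
                                            k = smote_k, seed = seed + 1000L)
  } else {
    train_aug <- train
  }

  assert_no_leakage(train_aug, test$subject_ids, train$subject_ids)

  sc_train <- cohort_sc(train_aug)
  sc_test <- cohort_sc(test)

  if (is.null(config))
    config <- brainnet_config(D = cohort$B, seed = seed)
  model <- build_brainnet(config)
  fit <- brainnet_train(model, sc_train, attr(sc_train, "labels"))
  ev <- brainnet_evaluate(fit$model, sc_test, attr(sc_test, "labels"))

  data.frame(method = method, n_artificial = as.integer(n_artificial),
             seed = as.integer(seed),
             n_train = length(train_aug$subjects),
             n_test = length(test$subjects),
             accuracy = ev$accuracy,
             final_train_loss = utils::tail(fit$history$loss, 1) %||% NA_real_)
}

# Abort if any artificial subject's provenance references a test subject.
assert_no_leakage <- function(aug_cohort, test_ids, train_ids) {
  for (pv in aug_cohort$provenance) {
    if (identical(pv, "original")) next
    donors <- unlist(lapply(
      if (isTRUE(pv$per_feature)) pv$donors else list(pv),
      function(e) e$donors))
    if (any(donors %in% test_ids) || !all(donors %in% train_ids))
      stop("augmentation leakage: artificial sample has a donor outside the training split")
  }
  invisible(TRUE)
}

#' Sweep artificial-sample counts and augmentation methods
#'
#' Repeats \code{\link{run_session}} over a grid of artificial-sample
#' counts, methods and seeds (the repeated-session protocol of the
#' augmentation experiment), returning one tidy row per session. For GEMD
#' sessions the full-cohort IMF tensor is computed once per seed and the
#' training-split slices are reused across the grid.
#'
#' @param cohort,graph,split_spec,config,M,smote_k as in
#'   \code{\link{run_session}}.
#' @param n_grid integer vector of artificial-sample counts.
#' @param methods subset of \code{c("none", "gemd", "smote")}.
#' @param seeds integer vector of session seeds.
#' @return data frame with columns \code{session, method, n_artificial,
#'   seed, split, accuracy}.
#' @export
run_sweep <- function(cohort, graph, n_grid = c(0L, 50L),
                      methods = c("none", "gemd"), seeds = 1:10,
                      split_spec = list(type = "fixed",
                                        n_train_per_group = 7L),
                      config = NULL, M = 5L, smote_k = 5L) {
  rows <- list()
  session <- 0L
  imfs <- if ("gemd" %in% methods && any(n_grid > 0L))
    decompose_cohort(cohort, graph, M = M) else NULL
  for (seed in seeds) {
    for (method in methods) {
      ns <- if (method == "none") 0L else n_grid[n_grid > 0L]
      if (method != "none" && length(ns) == 0L) next
      for (n_art in ns) {
        session <- session + 1L
        rec <- run_session(cohort, graph, n_artificial = n_art,
                           method = method, seed = seed,
                           split_spec = split_spec, config = config,
                           M = M, smote_k = smote_k, imfs = imfs)
        rec$session <- session
        rec$split <- "fixed"
        rows[[session]] <- rec
      }
    }
  }
  out <- do.call(rbind, rows)
  out[, c("session", "method", "n_artificial", "seed", "split", "accuracy",
          "n_train", "n_test", "final_train_loss")]
}
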