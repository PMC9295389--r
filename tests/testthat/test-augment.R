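test_that("recombining all slots from one donor reconstructs that donor", {
  tc <- toy_cohort(B = 15, n_per_group = 3, seed = 51)
  co <- tc$cohort
  tens <- decompose_cohort(co, tc$graph, M = 5)
  # degenerate donor list: subject 2 contributes every slot
  art <- make_artificial_sample(tens, rep(2L, 5), perm = 1:5, replace = TRUE)
  expect_equal(art, co$subjects[[2]], tolerance = 1e-8)
  # identical donors -> output equals the shared matrix
  co_same <- new_cohort(rep(list(co$subjects[[1]]), 5), rep("gifted", 5))
  tens_same <- decompose_cohort(co_same, tc$graph, M = 5)
  art_same <- make_artificial_sample(tens_same, c(3L, 1L, 5L, 2L, 4L),
                                     perm = c(2L, 4L, 1L, 5L, 3L))
  expect_equal(art_same, co$subjects[[1]], tolerance = 1e-8)
})

test_that("recombination equals a scripted sum over permuted IMF picks", {
  tc <- toy_cohort(B = 12, n_per_group = 5, seed = 52)
  co <- tc$cohort
  tens <- decompose_cohort(co, tc$graph, M = 5)
  donors <- c(4L, 1L, 7L, 9L, 2L)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  got <- make_artificial_sample(tens, donors, perm = perm)
  want <- matrix(0, co$B, co$F)
  for (m in 1:5) {
    for (b in seq_len(co$B)) for (f in seq_len(co$F)) {
      want[b, f] <- want[b, f] + tens[perm[m], b, f, donors[m]]
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("recombination is invariant to donor-list ordering given the same assignment", {
  tc <- toy_cohort(B = 12, n_per_group = 5, seed = 53)
  tens <- decompose_cohort(tc$cohort, tc$graph, M = 5)
  donors <- c(2L, 5L, 1L, 8L, 4L)
  perm <- c(4L, 1L, 5L, 3L, 2L)
  a <- make_artificial_sample(tens, donors, perm = perm)
  # reorder the (donor, slot) pairs: same assignment, different listing
  ord <- c(3L, 1L, 5L, 2L, 4L)
  b <- make_artificial_sample(tens, donors[ord], perm = perm[ord])
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("augmented training sets are labelled, sized and reproducible", {
  tc <- toy_cohort(B = 12, n_per_group = 7, seed = 54)
  co <- tc$cohort
  tens <- decompose_cohort(co, tc$graph, M = 5)
  expect_identical(augment_training_set(co, tens, 0L), co)
  aug <- augment_training_set(co, tens, 10L, seed = 7)
  expect_length(aug$subjects, 14 + 20)
  expect_identical(sum(aug$labels == "gifted"), 17L)
  expect_identical(sum(aug$labels == "control"), 17L)
  # artificial samples never mix groups: donors all carry the sample label
  for (i in seq_along(aug$provenance)) {
    pv <- aug$provenance[[i]]
    if (identical(pv, "original")) next
    donor_groups <- co$labels[match(pv$donors, co$subject_ids)]
    expect_true(all(donor_groups == aug$labels[i]))
    expect_identical(sort(pv$perm), 1:5)
    expect_identical(anyDuplicated(pv$donors), 0L)
  }
  # determinism
  aug2 <- augment_training_set(co, tens, 10L, seed = 7)
  expect_equal(aug$subjects, aug2$subjects)
  expect_identical(aug$subject_ids, aug2$subject_ids)
  # a different seed gives different artificial data
  aug3 <- augment_training_set(co, tens, 10L, seed = 8)
  expect_false(isTRUE(all.equal(aug$subjects[[15]], aug3$subjects[[15]])))
})

test_that("artificial samples differ from all donors on perturbed cohorts", {
  tc <- toy_cohort(B = 12, n_per_group = 6, seed = 55, noise = 0.5)
  co <- tc$cohort
  tens <- decompose_cohort(co, tc$graph, M = 5)
  aug <- augment_training_set(co, tens, 5L, seed = 3)
  art_idx <- which(!vapply(aug$provenance, identical, logical(1), "original"))
  for (i in art_idx) {
    for (p in seq_along(co$subjects)) {
      expect_gt(max(abs(aug$subjects[[i]] - co$subjects[[p]])), 1e-6)
    }
  }
})

test_that("augmentation errors are informative", {
  tc <- toy_cohort(B = 12, n_per_group = 3, seed = 56)
  co <- tc$cohort
  tens <- decompose_cohort(co, tc$graph, M = 5)
  expect_error(augment_training_set(co, tens, -1L), "n_per_group")
  expect_error(augment_training_set(co, tens, 2L), "reduce M|replace")
  expect_silent(aug <- augment_training_set(co, tens, 2L, replace = TRUE))
  expect_length(aug$subjects, 10)
  expect_error(make_artificial_sample(tens, c(1L, 1L, 2L, 3L, 2L)),
               "distinct")
  expect_error(make_artificial_sample(tens, 1:4), "donors")
  expect_error(make_artificial_sample(tens, 1:5, perm = c(1, 1, 2, 3, 4)),
               "permutation")
})

test_that("SMOTE samples lie on segments between neighbors", {
  # identical samples collapse every synthetic point onto them
  X <- rbind(c(1, 2), c(1, 2))
  syn <- smote_sample(X, n = 4, k = 1, seed = 1)
  expect_true(all(abs(sweep(syn, 2, c(1, 2))) < 1e-12))
  # toy 2-D points: each synthetic point sits on a base-neighbor segment
  P <- rbind(c(0, 0), c(1, 0), c(0, 1))
  syn2 <- smote_sample(P, n = 20, k = 2, seed = 2)
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  for (i in seq_len(nrow(syn2))) {
    dmin <- min(apply(expand.grid(1:3, 1:3), 1, function(ij) {
      if (ij[1] == ij[2]) return(Inf)
      seg_dist(syn2[i, ], P[ij[1], ], P[ij[2], ])
    }))
    expect_lt(dmin, 1e-10)
  }
  expect_error(smote_sample(P, n = 2, k = 3), "smaller")
  # determinism
  expect_equal(smote_sample(P, n = 5, k = 2, seed = 9),
               smote_sample(P, n = 5, k = 2, seed = 9))
})

test_that("SMOTE cohort augmentation mirrors the GEMD interface", {
  tc <- toy_cohort(B = 12, n_per_group = 4, seed = 57)
  co <- tc$cohort
  expect_identical(augment_training_set_smote(co, 0L), co)
  aug <- augment_training_set_smote(co, 3L, k = 2, seed = 4)
  expect_length(aug$subjects, 8 + 6)
  expect_identical(sum(aug$labels == "gifted"), 7L)
  art <- which(startsWith(aug$subject_ids, "smote_"))
  expect_length(art, 6)
})
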