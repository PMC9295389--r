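test_that("extrema follow the strict neighborhood definition", {
  g <- make_toy_graph("path", 3)
  ext <- find_extrema(c(0, 1, 0), g)
  expect_identical(ext$maxima, 2L)
  expect_setequal(ext$minima, c(1L, 3L))
  # constant signal: strict inequality fails everywhere
  ext0 <- find_extrema(rep(2, 3), g)
  expect_length(ext0$minima, 0)
  expect_length(ext0$maxima, 0)
  # one strict global peak on a complete graph -> exactly one maximum
  coords <- matrix(rnorm(3 * 8, sd = 0.1), ncol = 3)
  gk <- build_region_graph(coords, delta = 10)  # complete
  x <- c(5, rnorm(7))
  expect_identical(find_extrema(x, gk)$maxima, 1L)
  expect_error(find_extrema(1:4, g), "length")
})

test_that("extrema match the brute-force oracle on random graphs", {
  set.seed(21)
  for (rep in 1:5) {
    g <- suppressWarnings(
      make_toy_graph("geometric", 15, delta = 0.55, seed = rep))
    x <- rnorm(15)
    got <- find_extrema(x, g)
    want <- oracle_extrema(x, g$weights)
    expect_identical(got$minima, want$minima)
    expect_identical(got$maxima, want$maxima)
  }
})

test_that("Dirichlet interpolation solves the constrained problem", {
  # hand-solved path: endpoints 0 and 2, harmonic middle value is 1
  g <- make_toy_graph("path", 3)
  s <- graph_interpolate(c(1, 3), c(0, 2), g)
  expect_equal(s, c(0, 1, 2), tolerance = 1e-12)
  # K = all nodes is the identity
  expect_equal(graph_interpolate(1:3, c(4, 5, 6), g), c(4, 5, 6))
  # constants are harmonic
  gg <- make_toy_graph("geometric", 12, delta = 0.6, seed = 3)
  expect_equal(graph_interpolate(c(2, 7), c(3, 3), gg), rep(3, 12),
               tolerance = 1e-10)
  expect_error(graph_interpolate(integer(0), numeric(0), g), "nonempty")
})

test_that("interpolation agrees with the dense KKT oracle on B <= 20", {
  set.seed(22)
  graphs <- list(make_toy_graph("path", 7),
                 make_toy_graph("ring", 11),
                 make_toy_graph("grid", 12),
                 make_toy_graph("geometric", 20, delta = 0.55, seed = 5))
  for (g in graphs) {
    B <- n_regions(g)
    for (rep in 1:3) {
      k <- sample(2:(B - 1), 1)
      K <- sort(sample(B, k))
      vals <- rnorm(k)
      s <- graph_interpolate(K, vals, g)
      expect_equal(s, oracle_interpolate_kkt(K, vals, g$laplacian),
                   tolerance = 1e-8)
      # pinned exactly, harmonic at unknowns
      expect_equal(s[K], vals)
      U <- setdiff(seq_len(B), K)
      expect_lt(max(abs((g$laplacian %*% s)[U])), 1e-8)
    }
  }
})

test_that("harmonic maximum principle holds on connected graphs", {
  set.seed(23)
  for (rep in 1:10) {
    g <- make_toy_graph("ring", 15)
    K <- sort(sample(15, sample(2:10, 1)))
    vals <- rnorm(length(K))
    s <- graph_interpolate(K, vals, g)
    expect_gte(min(s), min(vals) - 1e-10)
    expect_lte(max(s), max(vals) + 1e-10)
  }
})

test_that("components without a known node are filled with the known mean", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(50, 0, 0), c(51, 0, 0))
  g <- suppressWarnings(build_region_graph(coords, delta = 2))
  expect_warning(s <- graph_interpolate(c(1, 2), c(1, 3), g),
                 "no known node")
  expect_equal(s, c(1, 3, 2, 2))
})

test_that("envelopes pin the signal at its extrema and are sign-symmetric", {
  g <- make_toy_graph("ring", 12)
  set.seed(24)
  x <- sin(seq(0, 4 * pi, length.out = 12)) + rnorm(12, sd = 0.2)
  env <- envelopes(x, g)
  ext <- find_extrema(x, g)
  expect_equal(env$e_max[ext$maxima], x[ext$maxima])
  expect_equal(env$e_min[ext$minima], x[ext$minima])
  # dense-solve oracle for both envelopes
  expect_equal(env$e_max,
               oracle_interpolate_kkt(ext$maxima, x[ext$maxima], g$laplacian),
               tolerance = 1e-8)
  # sign symmetry e_max(x) = -e_min(-x)
  env_neg <- envelopes(-x, g)
  expect_equal(env$e_max, -env_neg$e_min, tolerance = 1e-10)
  # spike on a constant background passes through the spike value
  gk <- make_toy_graph("grid", 9)
  xs <- rep(0, 9); xs[5] <- 4; xs[1] <- -1
  es <- envelopes(xs, gk)
  expect_equal(es$e_max[5], 4)
  # a signal with no extrema of one kind terminates sifting: on a path,
  # (0, 0, 1) has a maximum at node 3 but no minimum (plateau ties)
  gp <- make_toy_graph("path", 3)
  expect_error(envelopes(c(0, 0, 1), gp), class = "gemd_monotone")
})

test_that("mean envelope is the elementwise average", {
  set.seed(25)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(mean_envelope(a, b), (a + b) / 2)
  expect_equal(mean_envelope(-a, a), rep(0, 10))
  expect_equal(mean_envelope(a, a), a)
  expect_error(mean_envelope(a, b[-1]), "lengths")
})

test_that("decomposition reconstructs the input and handles degenerate input", {
  g <- make_toy_graph("ring", 16)
  # constant signal: zero IMFs, residual = input
  st <- gemd_decompose(rep(3, 16), g)
  expect_identical(st$n_extracted, 0L)
  expect_equal(st$residual, rep(3, 16))
  expect_true(all(st$imfs == 0))
  # random signals reconstruct to 1e-8 relative
  set.seed(26)
  for (rep in 1:5) {
    x <- rnorm(16)
    st <- gemd_decompose(x, g)
    expect_lt(max(abs(colSums(st$imfs) + st$residual - x)) / max(abs(x)),
              1e-8)
    # zero-padding occupies the trailing slots
    if (st$n_extracted < st$max_imfs)
      expect_true(all(st$imfs[(st$n_extracted + 1):st$max_imfs, ] == 0))
    # every extracted IMF oscillates (has both kinds of extrema)
    for (i in seq_len(st$n_extracted)) {
      ext <- find_extrema(st$imfs[i, ], g)
      expect_gt(length(ext$minima), 0)
      expect_gt(length(ext$maxima), 0)
    }
  }
})

test_that("decomposition is 1-homogeneous under positive scaling", {
  g <- make_toy_graph("geometric", 20, delta = 0.5, seed = 9)
  set.seed(27)
  x <- rnorm(20)
  st1 <- gemd_decompose(x, g)
  st2 <- gemd_decompose(2.5 * x, g)
  expect_identical(st1$n_extracted, st2$n_extracted)
  expect_equal(2.5 * st1$imfs, st2$imfs, tolerance = 1e-9)
  expect_equal(2.5 * st1$residual, st2$residual, tolerance = 1e-9)
})

test_that("first IMF captures the high-graph-frequency component", {
  g <- make_toy_graph("ring", 24)
  eig <- eigen(g$laplacian, symmetric = TRUE)
  # columns sorted by decreasing eigenvalue: [,1] high frequency, last low
  hi <- eig$vectors[, 2]
  lo <- eig$vectors[, 22]
  x <- hi + lo
  st <- gemd_decompose(x, g)
  expect_gt(st$n_extracted, 0)
  imf1 <- st$imfs[1, ]
  expect_gt(abs(cor(imf1, hi)), abs(cor(imf1, lo)))
})

test_that("cohort decomposition has the M x B x F x P contract", {
  tc <- toy_cohort(B = 15, n_per_group = 2, seed = 31)
  co <- tc$cohort
  tens <- decompose_cohort(co, tc$graph, M = 5)
  expect_identical(dim(tens), c(5L, 15L, 7L, 4L))
  # summing over the IMF axis reproduces every subject (residual folded)
  for (p in seq_len(4)) {
    rec <- apply(tens[, , , p], c(2, 3), sum)
    expect_equal(rec, co$subjects[[p]], tolerance = 1e-8)
  }
  expect_lt(attr(tens, "max_reconstruction_error"), 1e-8)
  # constant features: nothing extracted, residual (= input) in last slot
  const <- new_cohort(list(matrix(2, 15, 3)), "control")
  tens_c <- decompose_cohort(const, tc$graph, M = 5)
  expect_true(all(tens_c[1:4, , , 1] == 0))
  expect_equal(tens_c[5, , , 1], matrix(2, 15, 3))
  # shape mismatch is an input error
  expect_error(decompose_cohort(const, make_toy_graph("path", 8)), "match")
})
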