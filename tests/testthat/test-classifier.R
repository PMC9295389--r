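test_that("connectome filters match brute-force loops and trivial cases", {
  set.seed(71)
  for (D in c(1, 2, 5, 10)) {
    X <- matrix(rnorm(D * D), D, D)
    c1 <- rnorm(D); c2 <- rnorm(D)
    expect_equal(e2e_filter(X, c1, c2), oracle_e2e(X, c1, c2),
                 tolerance = 1e-6)
    expect_equal(e2n_filter(X, c1), oracle_e2n(X, c1), tolerance = 1e-6)
    v <- rnorm(D)
    expect_equal(n2g_filter(v, c2), oracle_n2g(v, c2), tolerance = 1e-6)
  }
  # worked example: X = [[1,2],[3,4]], c1 = c2 = (1,1) -> out[1,1] = 7
  X <- matrix(c(1, 3, 2, 4), 2, 2)
  out <- e2e_filter(X, c(1, 1), c(1, 1))
  expect_equal(out[1, 1], (1 + 2) + (1 + 3))
  # D = 1 degenerate case
  expect_equal(e2e_filter(matrix(5), 2, 3), matrix(25))
  # zero input stays zero; ones-kernel E2N gives row sums
  expect_true(all(e2e_filter(matrix(0, 4, 4), rnorm(4), rnorm(4)) == 0))
  X4 <- matrix(rnorm(16), 4, 4)
  expect_equal(e2n_filter(X4, rep(1, 4)), rowSums(X4))
  expect_equal(e2n_filter(X4, c(0, 0, 1, 0)), X4[, 3])
  expect_equal(n2g_filter(rep(0, 4), rnorm(4)), 0)
  expect_error(e2e_filter(X4, rnorm(3), rnorm(4)), "mismatch")
})

test_that("the E2E filter is linear", {
  set.seed(72)
  D <- 6
  X <- matrix(rnorm(D^2), D); Y <- matrix(rnorm(D^2), D)
  c1 <- rnorm(D); c2 <- rnorm(D)
  expect_equal(e2e_filter(2 * X - 3 * Y, c1, c2),
               2 * e2e_filter(X, c1, c2) - 3 * e2e_filter(Y, c1, c2),
               tolerance = 1e-10)
})

test_that("model construction is seeded and parameter count scales", {
  cfg <- brainnet_config(D = 8, epochs = 5, seed = 3)
  m1 <- build_brainnet(cfg)
  m2 <- build_brainnet(cfg)
  expect_equal(m1$par, m2$par)
  # forward pass returns a probability
  X <- matrix(rnorm(64), 8, 8)
  y <- brainnet_predict(m1, X)
  expect_true(y > 0 && y < 1)
  # doubling E2E channels doubles the E2E parameter count
  cfg2 <- brainnet_config(D = 8, channels = c(e2e = 8L, e2n = 16L, n2g = 32L))
  m3 <- build_brainnet(cfg2)
  n_e2e <- function(m) length(m$par$e2e_r) + length(m$par$e2e_s) +
    length(m$par$e2e_b)
  expect_equal(n_e2e(m3), 2 * n_e2e(m1))
  expect_error(brainnet_config(D = 1), "D")
  expect_error(brainnet_config(D = 8, dense = c(16L, 2L)), "dense")
})

test_that("training overfits a small separable set and is well-behaved", {
  set.seed(73)
  D <- 8
  # separable: positive class has a strong block, negative the mirrored one
  mk <- function(cls) {
    M <- matrix(rnorm(D * D, sd = 0.3), D, D)
    if (cls == 1) M[1:3, 1:3] <- M[1:3, 1:3] + 2 else
      M[5:8, 5:8] <- M[5:8, 5:8] + 2
    M <- (M + t(M)) / 2
    M
  }
  labels <- rep(c(0, 1), each = 10)
  tens <- array(0, dim = c(20, D, D))
  for (i in 1:20) tens[i, , ] <- mk(labels[i])
  cfg <- brainnet_config(D = D, epochs = 150, batch_size = 8, seed = 5)
  model <- build_brainnet(cfg)
  fit <- brainnet_train(model, tens, labels)
  expect_true(all(is.finite(fit$history$loss)))
  expect_equal(tail(fit$history$accuracy, 1), 1.0)
  ev <- brainnet_evaluate(fit$model, tens, labels)
  expect_equal(ev$accuracy, 1.0)
  # zero epochs leave the model untouched
  fit0 <- brainnet_train(model, tens, labels, epochs = 0)
  expect_equal(fit0$model$par, model$par)
  # single-class training set errors
  expect_error(brainnet_train(model, tens, rep(1, 20)), "single class")
})

test_that("network memorizes shuffled labels (capacity probe)", {
  set.seed(74)
  D <- 8
  tens <- array(rnorm(16 * D * D), dim = c(16, D, D))
  labels <- sample(rep(c(0, 1), each = 8))
  cfg <- brainnet_config(D = D, epochs = 200, batch_size = 8, seed = 6)
  fit <- brainnet_train(build_brainnet(cfg), tens, labels)
  expect_gt(tail(fit$history$accuracy, 1), 0.5)
})

test_that("evaluation accuracy follows the 0.5 threshold rule", {
  cfg <- brainnet_config(D = 4, seed = 1)
  model <- build_brainnet(cfg)
  labels <- c(0, 1, 0, 1)
  # synthetic score check through the public contract
  scores <- c(0.1, 0.9, 0.2, 0.8)
  expect_equal(mean((scores > 0.5) == (labels == 1)), 1.0)
  expect_equal(mean((1 - scores > 0.5) == (labels == 1)), 0.0)
  # random scores on balanced labels hover near chance (Monte-Carlo)
  set.seed(75)
  acc <- replicate(400, {
    s <- runif(20)
    l <- rep(c(0, 1), 10)
    mean((s > 0.5) == (l == 1))
  })
  expect_lt(abs(mean(acc) - 0.5), 0.02)
})
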