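#' Configuration of the connectome convolutional classifier
#'
#' Architecture and optimizer settings for the edge-to-edge /
#' edge-to-node / node-to-graph network:
#' input (D x D SC matrix) -> E2E (4 channels) -> relu -> E2N (16 channels)
#' -> relu -> N2G (32 channels) -> dense (16) -> dense (1) -> sigmoid.
#' Training uses Adam (lr 0.001, beta1 0.9, beta2 0.999), binary
#' cross-entropy, 300 epochs and batch size 32 by default.
#'
#' @param D number of graph nodes (side of the input SC matrix).
#' @param channels named integer vector \code{c(e2e =, e2n =, n2g =)}.
#' @param dense integer vector of the two dense widths (second must be 1).
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param epochs,batch_size training schedule.
#' @param seed seed for weight initialization and batch shuffling.
#' @return list of class \code{brainnet_config}.
#' @export
brainnet_config <- function(D = 308L,
                            channels = c(e2e = 4L, e2n = 16L, n2g = 32L),
                            dense = c(16L, 1L),
                            lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                            epochs = 300L, batch_size = 32L, seed = 1L) {
  if (D < 2L) stop("'D' must be >= 2")
  if (any(channels < 1L) || length(channels) != 3L)
    stop("three positive channel counts required")
  if (length(dense) != 2L || dense[2] != 1L)
    stop("'dense' must be c(hidden, 1)")
  structure(list(D = as.integer(D),
                 channels = as.integer(channels) |>
                   stats::setNames(c("e2e", "e2n", "n2g")),
                 dense = as.integer(dense),
                 lr = lr, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "brainnet_config")
}

#' Edge-to-edge filter (single channel)
#'
#' The E2E kernel is the cross-shaped sum of a row kernel and a column
#' kernel: \code{out[i, j] = sum_k c1[k] X[i, k] + sum_k c2[k] X[k, j]},
#' i.e. each edge response combines the full row of its first endpoint with
#' the full column of its second.
#'
#' @param X D x D matrix.
#' @param c1 length-D row kernel.
#' @param c2 length-D column kernel.
#' @return D x D matrix.
#' @export
e2e_filter <- function(X, c1, c2) {
  X <- as.matrix(X)
  D <- nrow(X)
  if (ncol(X) != D || length(c1) != D || length(c2) != D)
    stop("kernel/input shape mismatch")
  row_part <- as.vector(X %*% c1)      # depends on i only
  col_part <- as.vector(crossprod(X, c2))  # depends on j only
  matrix(row_part, D, D) + matrix(col_part, D, D, byrow = TRUE)
}

#' Edge-to-node filter (single channel)
#'
#' Assigns each node the weighted sum of its edges:
#' \code{out[i] = sum_k c1[k] X[i, k]}.
#'
#' @param X D x D matrix.
#' @param c1 length-D kernel.
#' @return length-D numeric vector.
#' @export
e2n_filter <- function(X, c1) {
  X <- as.matrix(X)
  if (ncol(X) != length(c1)) stop("kernel/input shape mismatch")
  as.vector(X %*% c1)
}

#' Node-to-graph filter (single channel)
#'
#' Reduces a node vector to one graph-level response:
#' \code{out = sum_k c2[k] v[k]}.
#'
#' @param v length-D node vector.
#' @param c2 length-D kernel.
#' @return scalar.
#' @export
n2g_filter <- function(v, c2) {
  if (length(v) != length(c2)) stop("kernel/input shape mismatch")
  sum(c2 * v)
}

#' Build an initialized network
#'
#' Allocates and seeds all weights. Initialization is scaled-normal
#' (He-style: sd = sqrt(2 / fan_in)) so ReLU activations keep unit-order
#' variance; biases start at zero. Given the same config (including seed)
#' the initial weights are identical across runs.
#'
#' @param config a \code{\link{brainnet_config}}.
#' @return object of class \code{brainnet}: list of parameter matrices plus
#'   the config and the total parameter count \code{n_params}.
#' @export
build_brainnet <- function(config) {
  stopifnot(inherits(config, "brainnet_config"))
  D <- config$D
  C1 <- config$channels[["e2e"]]
  C2 <- config$channels[["e2n"]]
  C3 <- config$channels[["n2g"]]
  H1 <- config$dense[1]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  gauss <- function(nr, nc, fan_in)
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
  par <- list(
    e2e_r = gauss(D, C1, 2 * D),      # row kernels, one column per channel
    e2e_s = gauss(D, C1, 2 * D),      # column kernels
    e2e_b = numeric(C1),
    e2n_W = gauss(C1 * D, C2, C1 * D),  # rows blocked by channel then node
    e2n_b = numeric(C2),
    n2g_W = gauss(C2 * D, C3, C2 * D),
    n2g_b = numeric(C3),
    d1_W = gauss(C3, H1, C3),
    d1_b = numeric(H1),
    d2_W = gauss(H1, 1, H1),
    d2_b = numeric(1))
  n_params <- sum(vapply(par, length, integer(1)))
  structure(list(par = par, config = config, n_params = n_params),
            class = "brainnet")
}

#' @export
print.brainnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "brainnet: D = %d, E2E %d -> E2N %d -> N2G %d -> dense %d -> 1 (%d parameters)\n",
    cfg$D, cfg$channels[["e2e"]], cfg$channels[["e2n"]],
    cfg$channels[["n2g"]], cfg$dense[1], x$n_params))
  invisible(x)
}

# Forward pass for one sample. Returns the prediction and, when
# keep_cache = TRUE, the intermediate activations needed by the backward
# pass. Z is stored as a D x (C1*D) matrix whose c-th column block is the
# rectified E2E output of channel c.
brainnet_forward_one <- function(par, X, keep_cache = FALSE) {
  D <- nrow(X)
  C1 <- ncol(par$e2e_r)
  A <- X %*% par$e2e_r              # D x C1, row part
  Bm <- crossprod(X, par$e2e_s)     # D x C1, column part
  Z <- matrix(0, D, C1 * D)
  for (c in seq_len(C1)) {
    H <- matrix(A[, c], D, D) + matrix(Bm[, c], D, D, byrow = TRUE) +
      par$e2e_b[c]
    Z[, ((c - 1) * D + 1):(c * D)] <- pmax(H, 0)
  }
  v <- Z %*% par$e2n_W + matrix(par$e2n_b, D, ncol(par$e2n_W), byrow = TRUE)
  u <- pmax(v, 0)                   # D x C2
  g <- as.vector(crossprod(par$n2g_W, as.vector(u))) + par$n2g_b
  r1 <- pmax(g, 0)                  # C3
  h_pre <- as.vector(crossprod(par$d1_W, r1)) + par$d1_b
  h <- pmax(h_pre, 0)               # H1
  logit <- sum(par$d2_W * h) + par$d2_b
  y <- 1 / (1 + exp(-logit))
  if (!keep_cache) return(list(y = y))
  list(y = y, X = X, Z = Z, v = v, u = u, g = g, r1 = r1,
       h_pre = h_pre, h = h)
}

# Backward pass for one sample: returns the gradient of the BCE loss with
# respect to every parameter, given the forward cache and the 0/1 target.
brainnet_backward_one <- function(par, cache, target) {
  D <- nrow(cache$X)
  C1 <- ncol(par$e2e_r)
  dlogit <- cache$y - target            # BCE + sigmoid
  g_d2_W <- cache$h * dlogit
  g_d2_b <- dlogit
  dh <- as.vector(par$d2_W) * dlogit
  dh[cache$h_pre <= 0] <- 0
  g_d1_W <- outer(cache$r1, dh)
  g_d1_b <- dh
  dr1 <- as.vector(par$d1_W %*% dh)
  dg <- dr1 * (cache$g > 0)
  uvec <- as.vector(cache$u)
  g_n2g_W <- outer(uvec, dg)
  g_n2g_b <- dg
  du <- matrix(as.vector(par$n2g_W %*% dg), D)   # D x C2
  dv <- du * (cache$v > 0)
  g_e2n_W <- crossprod(cache$Z, dv)
  g_e2n_b <- colSums(dv)
  dZ <- tcrossprod(dv, par$e2n_W)                # D x (C1*D)
  dZ[cache$Z <= 0] <- 0
  da <- matrix(0, D, C1)
  db <- matrix(0, D, C1)
  g_e2e_b <- numeric(C1)
  for (c in seq_len(C1)) {
    blk <- dZ[, ((c - 1) * D + 1):(c * D)]
    da[, c] <- rowSums(blk)
    db[, c] <- colSums(blk)
    g_e2e_b[c] <- sum(blk)
  }
  list(e2e_r = crossprod(cache$X, da),
       e2e_s = cache$X %*% db,
       e2e_b = g_e2e_b,
       e2n_W = g_e2n_W, e2n_b = g_e2n_b,
       n2g_W = g_n2g_W, n2g_b = g_n2g_b,
       d1_W = g_d1_W, d1_b = g_d1_b,
       d2_W = matrix(g_d2_W, ncol = 1), d2_b = g_d2_b)
}

#' Forward pass over a stack of SC matrices
#'
#' @param model a \code{brainnet}.
#' @param sc_tensor P x D x D array (or a single D x D matrix).
#' @return numeric vector of P predicted probabilities in (0, 1).
#' @export
brainnet_predict <- function(model, sc_tensor) {
  stopifnot(inherits(model, "brainnet"))
  if (is.matrix(sc_tensor))
    sc_tensor <- array(sc_tensor, dim = c(1, dim(sc_tensor)))
  P <- dim(sc_tensor)[1]
  vapply(seq_len(P), function(p)
    brainnet_forward_one(model$par, sc_tensor[p, , ])$y, numeric(1))
}

#' Train the network with Adam on binary cross-entropy
#'
#' Mini-batch training with the configured Adam hyperparameters. Batches
#' are reshuffled every epoch from a seeded stream, so training is
#' reproducible on CPU. The loss is checked for finiteness every epoch.
#'
#' @param model a \code{brainnet} from \code{\link{build_brainnet}}.
#' @param sc_tensor P x D x D array of (standardized) SC matrices.
#' @param labels numeric/integer 0-1 vector, or a character vector whose
#'   alphabetically second level is coded 1.
#' @param epochs,batch_size,lr optional overrides of the model config.
#' @return list with \code{model} (trained), and \code{history}, a data
#'   frame with per-epoch \code{loss} and \code{accuracy}.
#' @export
brainnet_train <- function(model, sc_tensor, labels, epochs = NULL,
                           batch_size = NULL, lr = NULL) {
  stopifnot(inherits(model, "brainnet"))
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  if (is.null(batch_size)) batch_size <- cfg$batch_size
  if (is.null(lr)) lr <- cfg$lr
  y <- encode_labels(labels)
  P <- dim(sc_tensor)[1]
  if (length(y) != P) stop("one label per SC matrix required")
  if (length(unique(y)) < 2L && epochs > 0L)
    stop("training set contains a single class")
  if (epochs == 0L)
    return(list(model = model,
                history = data.frame(epoch = integer(0), loss = numeric(0),
                                     accuracy = numeric(0))))

  par <- model$par
  mom <- lapply(par, function(p) p * 0)
  vel <- lapply(par, function(p) p * 0)
  b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- 1e-8
  step <- 0L
  hist_loss <- numeric(epochs)
  hist_acc <- numeric(epochs)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)  # decoupled from the init stream

  for (ep in seq_len(epochs)) {
    ord <- sample.int(P)
    ep_loss <- 0
    ep_correct <- 0
    for (start in seq(1, P, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, P)]
      grad <- NULL
      for (p_i in idx) {
        cache <- brainnet_forward_one(par, sc_tensor[p_i, , ],
                                      keep_cache = TRUE)
        gi <- brainnet_backward_one(par, cache, y[p_i])
        yp <- min(max(cache$y, 1e-12), 1 - 1e-12)
        ep_loss <- ep_loss - (y[p_i] * log(yp) + (1 - y[p_i]) * log(1 - yp))
        ep_correct <- ep_correct + as.integer((cache$y > 0.5) == (y[p_i] == 1))
        grad <- if (is.null(grad)) gi
                else mapply(`+`, grad, gi, SIMPLIFY = FALSE)
      }
      nb <- length(idx)
      step <- step + 1L
      for (nm in names(par)) {
        g <- grad[[nm]] / nb
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g^2
        mhat <- mom[[nm]] / (1 - b1^step)
        vhat <- vel[[nm]] / (1 - b2^step)
        par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    hist_loss[ep] <- ep_loss / P
    hist_acc[ep] <- ep_correct / P
    if (!is.finite(hist_loss[ep]))
      stop(sprintf("non-finite training loss at epoch %d", ep))
  }
  model$par <- par
  list(model = model,
       history = data.frame(epoch = seq_len(epochs), loss = hist_loss,
                            accuracy = hist_acc))
}

#' Evaluate a trained network
#'
#' @param model a \code{brainnet}.
#' @param sc_tensor P x D x D array.
#' @param labels 0-1 or two-level character labels.
#' @return list with \code{accuracy} (threshold 0.5) and \code{scores}.
#' @export
brainnet_evaluate <- function(model, sc_tensor, labels) {
  y <- encode_labels(labels)
  scores <- brainnet_predict(model, sc_tensor)
  list(accuracy = mean((scores > 0.5) == (y == 1)), scores = scores)
}

# Map labels to 0/1; character labels are coded by alphabetical order
# (first level -> 0). "gifted" vs "control": control = 0, gifted = 1.
encode_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.numeric(labels))
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) > 2L) stop("more than two label levels")
  as.numeric(as.character(labels) == lv[length(lv)])
}
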