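# Permutation-invariant point-cloud encoder: a shared per-point multilayer
# map (3 -> 64 -> 128 -> 1024, rectifier nonlinearities) followed by
# coordinate-wise max aggregation over points. Forward and backward passes
# are written directly in matrix algebra; optimisation uses Adam.

#' Initialise encoder weights
#'
#' He-style seeded initialisation of the shared per-point layers. The final
#' per-point width equals the pooled global feature width (1024).
#'
#' @param seed Integer seed.
#' @param dims Layer widths, input first (default `c(3, 64, 128, 1024)`).
#' @return An object of class `encoder_weights`: matrices `W1, W2, W3` and
#'   bias vectors `b1, b2, b3`.
#' @export
encoder_init <- function(seed = 1L, dims = c(3L, 64L, 128L, 1024L)) {
  stopifnot(length(dims) == 4L, dims[4] >= 1L)
  with_seed(seed, {
    layer <- function(din, dout) {
      matrix(stats::rnorm(din * dout, 0, sqrt(2 / din)), din, dout)
    }
    structure(
      list(W1 = layer(dims[1], dims[2]), b1 = rep(0, dims[2]),
           W2 = layer(dims[2], dims[3]), b2 = rep(0, dims[3]),
           W3 = layer(dims[3], dims[4]), b3 = rep(0, dims[4]),
           dims = dims, seed = as.integer(seed)),
      class = "encoder_weights"
    )
  })
}

#' @export
print.encoder_weights <- function(x, ...) {
  cat(sprintf("<encoder_weights> per-point map %s, max-pooled to %d\n",
              paste(x$dims, collapse = " -> "), x$dims[4]))
  invisible(x)
}

# forward pass keeping the intermediates needed for backpropagation.
# Rows are first put into a canonical (lexicographic) order: optimized
# matrix kernels round edge rows differently depending on their position,
# so without a canonical order the max-pooled feature would be permutation
# invariant only up to 1 ulp — the invariance contract is bitwise. Biases
# are folded into the matrix products via an appended ones column.
encoder_forward <- function(points, weights) {
  ord <- order(points[, 1], points[, 2], points[, 3])
  pts <- points[ord, , drop = FALSE]
  n <- nrow(pts)
  ones <- rep(1, n)
  A1 <- cbind(pts, ones) %*% rbind(weights$W1, weights$b1)
  H1 <- pmax(A1, 0)
  A2 <- cbind(H1, ones) %*% rbind(weights$W2, weights$b2)
  H2 <- pmax(A2, 0)
  F3 <- cbind(H2, ones) %*% rbind(weights$W3, weights$b3)
  arg <- max.col(t(F3), ties.method = "first")  # argmax point per feature
  phi <- F3[cbind(arg, seq_len(ncol(F3)))]
  list(phi = phi, cache = list(points = pts, ord = ord, n_in = nrow(points),
                               A1 = A1, H1 = H1, A2 = A2, H2 = H2, arg = arg))
}

#' Encode a point cloud as a global feature
#'
#' Applies the shared per-point map and takes the elementwise maximum over
#' points, yielding a fixed-length descriptor that is exactly invariant to
#' any permutation (or duplication) of the input rows.
#'
#' @param points N x 3 coordinate matrix with finite entries.
#' @param weights An `encoder_weights` object.
#' @return Numeric global feature vector of length `weights$dims[4]`
#'   (1024 by default).
#' @export
encode <- function(points, weights) {
  stopifnot(inherits(weights, "encoder_weights"))
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 1L) {
    stop("`points` must be an N x 3 matrix with N >= 1", call. = FALSE)
  }
  if (!all(is.finite(points))) stop("non-finite coordinate in `points`", call. = FALSE)
  encoder_forward(points, weights)$phi
}

# backpropagate d(loss)/d(phi) through the cached forward pass;
# the max-pool routes each feature's gradient to its argmax point.
# With input_grad = TRUE the gradient with respect to the input coordinates
# is returned as well (needed when the cloud itself is a function of
# upstream variables, as in the unrolled registration).
encoder_backward <- function(cache, weights, grad_phi, input_grad = FALSE) {
  n <- nrow(cache$points)
  k <- length(grad_phi)
  dF3 <- matrix(0, n, k)
  dF3[cbind(cache$arg, seq_len(k))] <- grad_phi
  dH2 <- dF3 %*% t(weights$W3)
  dA2 <- dH2 * (cache$A2 > 0)
  dH1 <- dA2 %*% t(weights$W2)
  dA1 <- dH1 * (cache$A1 > 0)
  out <- list(W1 = crossprod(cache$points, dA1), b1 = colSums(dA1),
              W2 = crossprod(cache$H1, dA2), b2 = colSums(dA2),
              W3 = crossprod(cache$H2, dF3), b3 = colSums(dF3))
  if (input_grad) {
    # undo the canonical row ordering so the gradient matches the caller's
    # original row layout
    dP <- dA1 %*% t(weights$W1)
    out$points <- matrix(0, cache$n_in, 3L)
    out$points[cache$ord, ] <- dP
  }
  out
}

# ---- Adam optimiser over a named list of parameter arrays ----

adam_init <- function(params) {
  zero <- lapply(params, function(p) p * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(state, params, grads, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  # bias corrections folded into two scalars to avoid full-size temporaries
  c2r <- sqrt(1 - beta2^state$t)
  lr_t <- lr * c2r / (1 - beta1^state$t)
  eps_t <- eps * c2r
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr_t * state$m[[nm]] / (sqrt(state$v[[nm]]) + eps_t)
  }
  list(state = state, params = params)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Serialise encoder weights to a versioned JSON file
#' @param weights An `encoder_weights` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_encoder_weights <- function(weights, path) {
  stopifnot(inherits(weights, "encoder_weights"))
  payload <- list(format = "eamreg_encoder_weights", version = 1L,
                  dims = weights$dims, seed = weights$seed,
                  W1 = weights$W1, b1 = weights$b1,
                  W2 = weights$W2, b2 = weights$b2,
                  W3 = weights$W3, b3 = weights$b3)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read encoder weights written by [write_encoder_weights()]
#' @param path Path to the weights file.
#' @return An `encoder_weights` object.
#' @export
read_encoder_weights <- function(path) {
  decode_encoder_weights(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Rebuild an `encoder_weights` object from its serialised payload
#' @param payload Named list as produced by [write_encoder_weights()].
#' @return An `encoder_weights` object.
#' @export
decode_encoder_weights <- function(payload) {
  if (!identical(payload$format, "eamreg_encoder_weights")) {
    stop("not an encoder weights file", call. = FALSE)
  }
  structure(
    list(W1 = as.matrix(payload$W1), b1 = as.numeric(payload$b1),
         W2 = as.matrix(payload$W2), b2 = as.numeric(payload$b2),
         W3 = as.matrix(payload$W3), b3 = as.numeric(payload$b3),
         dims = as.integer(payload$dims), seed = as.integer(payload$seed)),
    class = "encoder_weights"
  )
}

#' Pretrain the encoder on labelled shape classes
#'
#' Trains the encoder with a temporary linear classification head on a
#' corpus of labelled synthetic shapes (softmax cross-entropy, Adam,
#' minibatches), then discards the head. This gives the registration stage
#' pose-sensitive geometric features before it ever sees a voltage map.
#' The final training-set accuracy is recorded in attribute
#' `"train_accuracy"` and reported via `message()`.
#'
#' @param shapes List with `clouds` (list of N x 3 matrices) and `labels`
#'   (integer class ids); at least two distinct classes.
#' @param epochs Training epochs (0 returns the initialisation unchanged).
#' @param batch_size Minibatch size (default 16).
#' @param seed Integer seed for initialisation and shuffling.
#' @param lr Adam learning rate.
#' @param weights Optional `encoder_weights` to start from.
#' @param verbose Emit a per-run summary message?
#' @return Trained `encoder_weights` (classification head discarded).
#' @export
pretrain_encoder <- function(shapes, epochs, batch_size = 16L, seed = 1L,
                             lr = 1e-3, weights = NULL, verbose = FALSE) {
  labels <- as.integer(shapes$labels)
  clouds <- shapes$clouds
  classes <- sort(unique(labels))
  if (length(classes) < 2L) {
    stop("encoder pretraining needs at least 2 shape classes", call. = FALSE)
  }
  k <- length(classes)
  y <- match(labels, classes)
  if (is.null(weights)) weights <- encoder_init(seed)
  if (epochs == 0L) return(weights)
  dglob <- weights$dims[4]
  head <- with_seed(derive_seed(seed, 7L), list(
    Wh = matrix(stats::rnorm(dglob * k, 0, sqrt(1 / dglob)), dglob, k),
    bh = rep(0, k)
  ))
  params <- c(weights[c("W1", "b1", "W2", "b2", "W3", "b3")], head)
  opt <- adam_init(params)
  n <- length(clouds)
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(seed, 11L, ep), sample.int(n))
    for (start in seq(1L, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1L, n)]
      grads <- lapply(params, function(p) p * 0)
      for (i in batch) {
        fw <- encoder_forward(clouds[[i]],
                              structure(params[1:6], class = "encoder_weights",
                                        dims = NULL))
        z <- as.numeric(fw$phi %*% params$Wh) + params$bh
        p <- softmax(z)
        dz <- p
        dz[y[i]] <- dz[y[i]] - 1
        dz <- dz / length(batch)
        grads$Wh <- grads$Wh + outer(fw$phi, dz)
        grads$bh <- grads$bh + dz
        gphi <- as.numeric(params$Wh %*% dz)
        enc_g <- encoder_backward(fw$cache,
                                  structure(params[1:6], class = "encoder_weights"),
                                  gphi)
        for (nm in names(enc_g)) grads[[nm]] <- grads[[nm]] + enc_g[[nm]]
      }
      st <- adam_step(opt, params, grads, lr = lr)
      opt <- st$state
      params <- st$params
    }
  }
  out <- weights
  out[c("W1", "b1", "W2", "b2", "W3", "b3")] <-
    params[c("W1", "b1", "W2", "b2", "W3", "b3")]
  # training-set accuracy with the (about to be discarded) head
  correct <- 0L
  for (i in seq_len(n)) {
    phi <- encode(clouds[[i]], out)
    z <- as.numeric(phi %*% params$Wh) + params$bh
    if (which.max(z) == y[i]) correct <- correct + 1L
  }
  acc <- correct / n
  attr(out, "train_accuracy") <- acc
  if (verbose) {
    message(sprintf("encoder pretraining: %d clouds, %d epochs, training accuracy %.3f",
                    n, epochs, acc))
  }
  out
}
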