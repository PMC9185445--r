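# Two-layer MLP over ordered voltage vectors: fully-connected 406 -> 300,
# rectifier, dropout 0.4 (training only), fully-connected 300 -> 2, softmax.
# Trained by Adam on the printed two-term cross-entropy; a standard softmax
# cross-entropy is available behind a config flag.

#' Classifier configuration
#'
#' @param input_dim Input width (default 406, the common point count).
#' @param hidden_dim Hidden width (default 300).
#' @param dropout Dropout rate in `[0, 1)` applied after the hidden
#'   rectifier during training (default 0.4).
#' @param n_classes Number of classes (2).
#' @param epochs Training epochs (default 200).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Integer seed for initialisation and dropout masks.
#' @param use_standard_ce Use the standard softmax cross-entropy instead of
#'   the two-term binary form (default `FALSE`).
#' @param ensemble_weight Weight on the unipolar channel in the probability
#'   average (default 0.5).
#' @param weight_decay L2 penalty coefficient on the connection weights
#'   (default 0), applied as a decoupled decay in the Adam update.
#' @param balanced_bagging In the evaluation harness, average each fold's
#'   prediction over all balanced subfits obtained by dropping one majority
#'   example (default `TRUE`). A leave-one-out fold of a balanced cohort is
#'   imbalanced by one example; the held-out point's own class is then
#'   estimated from fewer examples, whose noisier fit systematically pushes
#'   pure-noise predictions toward the other class. Averaging over balanced
#'   subfits removes this asymmetry.
#' @param balance_classes Weight examples inversely to their class frequency
#'   during training (default `TRUE`)? Leave-one-out folds of a balanced
#'   cohort are always imbalanced by one example; unweighted fits then lean
#'   toward the training majority, which on small cohorts biases held-out
#'   accuracy well below chance under the null.
#' @return An object of class `mlp_config`.
#' @export
mlp_config <- function(input_dim = 406L, hidden_dim = 300L, dropout = 0.4,
                       n_classes = 2L, epochs = 200L, learning_rate = 1e-3,
                       seed = 1L, use_standard_ce = FALSE,
                       ensemble_weight = 0.5, balance_classes = TRUE,
                       weight_decay = 0, balanced_bagging = TRUE) {
  stopifnot(input_dim >= 1L, hidden_dim >= 1L, dropout >= 0, dropout < 1,
            n_classes == 2L, epochs >= 0L, learning_rate > 0,
            ensemble_weight >= 0, ensemble_weight <= 1, weight_decay >= 0)
  structure(
    list(input_dim = as.integer(input_dim), hidden_dim = as.integer(hidden_dim),
         dropout = dropout, n_classes = as.integer(n_classes),
         epochs = as.integer(epochs), learning_rate = learning_rate,
         seed = as.integer(seed), use_standard_ce = isTRUE(use_standard_ce),
         ensemble_weight = ensemble_weight,
         balance_classes = isTRUE(balance_classes),
         weight_decay = weight_decay,
         balanced_bagging = isTRUE(balanced_bagging)),
    class = "mlp_config"
  )
}

#' Initialise MLP weights
#' @param config An `mlp_config`.
#' @return An object of class `mlp_weights` (`W1, b1, W2, b2`).
#' @export
mlp_init <- function(config) {
  with_seed(config$seed, {
    structure(
      list(W1 = matrix(stats::rnorm(config$input_dim * config$hidden_dim, 0,
                                    sqrt(2 / config$input_dim)),
                       config$input_dim, config$hidden_dim),
           b1 = rep(0, config$hidden_dim),
           W2 = matrix(stats::rnorm(config$hidden_dim * config$n_classes, 0,
                                    sqrt(1 / config$hidden_dim)),
                       config$hidden_dim, config$n_classes),
           b2 = rep(0, config$n_classes)),
      class = "mlp_weights"
    )
  })
}

# forward pass; dropout_mask (0/1 over hidden units, pre-scaled) only during
# training
mlp_forward_cache <- function(x, weights, config, dropout_mask = NULL) {
  a1 <- as.numeric(x %*% weights$W1) + weights$b1
  h1 <- pmax(a1, 0)
  if (!is.null(dropout_mask)) h1 <- h1 * dropout_mask
  z <- as.numeric(h1 %*% weights$W2) + weights$b2
  y <- softmax(z)
  list(y = y, z = z, h1 = h1, a1 = a1)
}

#' MLP forward pass
#'
#' Fully-connected, rectifier, dropout (active only when `training = TRUE`,
#' inverted scaling), fully-connected, softmax. Inference is deterministic.
#'
#' @param x Numeric input vector of length `config$input_dim` (an
#'   `ordered_voltage_vector` works directly).
#' @param weights `mlp_weights`.
#' @param config `mlp_config`.
#' @param training Apply dropout? Uses the current RNG stream.
#' @return A `prediction`: list with `probabilities` (length 2, summing to
#'   1), `predicted_class` (0/1; ties go to class 0) and `patient_id`.
#' @export
mlp_forward <- function(x, weights, config, training = FALSE) {
  pid <- attr(x, "patient_id")
  x <- as.numeric(x)
  if (length(x) != config$input_dim) {
    stop(sprintf("input has length %d; expected %d", length(x),
                 config$input_dim), call. = FALSE)
  }
  mask <- NULL
  if (training && config$dropout > 0) {
    keep <- stats::rbinom(config$hidden_dim, 1L, 1 - config$dropout)
    mask <- keep / (1 - config$dropout)
  }
  fw <- mlp_forward_cache(x, weights, config, mask)
  prediction(fw$y, pid)
}

prediction <- function(probabilities, patient_id = NA_character_) {
  structure(
    list(probabilities = probabilities,
         predicted_class = as.integer(probabilities[2] > probabilities[1]),
         patient_id = if (is.null(patient_id)) NA_character_ else patient_id),
    class = "prediction"
  )
}

#' Two-term binary cross-entropy over output units
#'
#' `-sum_j [ t_j log(y_j) + (1 - t_j) log(1 - y_j) ]`: the sum over both
#' softmax outputs of the binary cross-entropy terms, so the uniform binary
#' prediction scores `2 * log(2)`. Log arguments are clamped at 1e-12.
#'
#' @param y Predicted probability vector.
#' @param t One-hot target vector of the same length.
#' @return Nonnegative scalar loss.
#' @export
cross_entropy <- function(y, t) {
  stopifnot(length(y) == length(t))
  clamp <- function(v) pmin(pmax(v, 1e-12), 1 - 1e-12)
  -sum(t * log(clamp(y)) + (1 - t) * log(clamp(1 - y)))
}

# gradient of the configured loss with respect to the logits z
loss_grad_logits <- function(y, t, use_standard_ce) {
  if (use_standard_ce) return(y - t)
  clamp <- function(v) pmin(pmax(v, 1e-12), 1 - 1e-12)
  dy <- -t / clamp(y) + (1 - t) / clamp(1 - y)
  y * (dy - sum(dy * y))  # softmax Jacobian-vector product
}

#' Train the MLP classifier
#'
#' Full-batch Adam minimisation of the configured cross-entropy over the
#' training set, with seeded initialisation and seeded dropout masks.
#'
#' @param X Numeric matrix, one example per row (`config$input_dim` columns).
#' @param labels Binary 0/1 vector; both classes must be present.
#' @param config `mlp_config`.
#' @return Trained `mlp_weights` with attribute `"loss_trace"` (mean loss
#'   per epoch). `epochs = 0` returns the initialisation.
#' @export
train_mlp <- function(X, labels, config) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (nrow(X) < 2L) stop("training needs at least 2 examples", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("training set contains a single class", call. = FALSE)
  }
  weights <- mlp_init(config)
  if (config$epochs == 0L) return(weights)
  n <- nrow(X)
  targets <- cbind(1 - labels, labels)  # one-hot, class order (0, 1)
  # per-example weights, mean 1; inverse class frequency when balancing
  ex_w <- rep(1, n)
  if (isTRUE(config$balance_classes)) {
    counts <- table(factor(labels, levels = c(0L, 1L)))
    ex_w <- n / (2 * as.numeric(counts[as.character(labels)]))
  }
  params <- unclass(weights)
  opt <- adam_init(params)
  loss_trace <- numeric(config$epochs)
  clamp <- function(v) pmin(pmax(v, 1e-12), 1 - 1e-12)
  with_seed(derive_seed(config$seed, 77L), {
    for (ep in seq_len(config$epochs)) {
      # full-batch forward, one dropout mask per example
      A1 <- sweep(X %*% params$W1, 2L, params$b1, "+")
      H1 <- pmax(A1, 0)
      if (config$dropout > 0) {
        mask <- matrix(stats::rbinom(n * config$hidden_dim, 1L,
                                     1 - config$dropout) / (1 - config$dropout),
                       n, config$hidden_dim)
        H1 <- H1 * mask
      }
      Z <- sweep(H1 %*% params$W2, 2L, params$b2, "+")
      Zs <- Z - apply(Z, 1L, max)
      E <- exp(Zs)
      Y <- E / rowSums(E)
      loss_trace[ep] <- -mean(ex_w * rowSums(targets * log(clamp(Y)) +
                                               (1 - targets) * log(clamp(1 - Y))))
      if (config$use_standard_ce) {
        dZ <- ex_w * (Y - targets) / n
      } else {
        dY <- -targets / clamp(Y) + (1 - targets) / clamp(1 - Y)
        dZ <- ex_w * Y * (dY - rowSums(dY * Y)) / n  # softmax Jacobian, per row
      }
      grads <- list(W1 = NULL, b1 = NULL, W2 = crossprod(H1, dZ),
                    b2 = colSums(dZ))
      dH1 <- dZ %*% t(params$W2)
      if (config$dropout > 0) dH1 <- dH1 * mask
      dA1 <- dH1 * (A1 > 0)
      grads$W1 <- crossprod(X, dA1)
      grads$b1 <- colSums(dA1)
      st <- adam_step(opt, params, grads, lr = config$learning_rate)
      opt <- st$state
      params <- st$params
      if (config$weight_decay > 0) {
        decay <- 1 - config$learning_rate * config$weight_decay
        params$W1 <- params$W1 * decay
        params$W2 <- params$W2 * decay
      }
    }
  })
  out <- structure(params, class = "mlp_weights")
  attr(out, "loss_trace") <- loss_trace
  out
}

#' Average two channel predictions for one patient
#'
#' Componentwise weighted average of the unipolar and bipolar classifiers'
#' probabilities; the predicted class is the argmax with ties broken toward
#' class 0.
#'
#' @param p_uni,p_bi `prediction`s for the same patient.
#' @param weight Weight on the unipolar prediction (default 0.5).
#' @return The ensemble `prediction`.
#' @export
ensemble_predict <- function(p_uni, p_bi, weight = 0.5) {
  if (!identical(p_uni$patient_id, p_bi$patient_id)) {
    stop("ensemble inputs refer to different patients", call. = FALSE)
  }
  prediction(weight * p_uni$probabilities + (1 - weight) * p_bi$probabilities,
             p_uni$patient_id)
}
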