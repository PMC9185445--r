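# Two-layer MLP classifier, printed-form cross-entropy, ensemble averaging.

test_that("the forward pass is a softmax two-layer network", {
  cfg <- mlp_config(input_dim = 10L, hidden_dim = 6L, seed = 1L)
  x <- eamreg:::with_seed(2L, rnorm(10))

  # zero weights give the uniform prediction
  w0 <- structure(list(W1 = matrix(0, 10, 6), b1 = rep(0, 6),
                       W2 = matrix(0, 6, 2), b2 = rep(0, 2)),
                  class = "mlp_weights")
  p <- mlp_forward(x, w0, cfg)
  expect_equal(p$probabilities, c(0.5, 0.5))
  expect_equal(p$predicted_class, 0L)  # tie goes to class 0

  # inference is deterministic (no dropout)
  w <- mlp_init(cfg)
  expect_identical(mlp_forward(x, w, cfg), mlp_forward(x, w, cfg))

  # independent hand-rolled forward pass
  h <- pmax(as.numeric(x %*% w$W1) + w$b1, 0)
  z <- as.numeric(h %*% w$W2) + w$b2
  expect_equal(mlp_forward(x, w, cfg)$probabilities,
               exp(z) / sum(exp(z)), tolerance = 1e-10)
  expect_equal(sum(mlp_forward(x, w, cfg)$probabilities), 1, tolerance = 1e-9)

  expect_error(mlp_forward(rnorm(9), w, cfg), "length")
})

test_that("cross-entropy implements the two-term binary form", {
  expect_equal(cross_entropy(c(0.5, 0.5), c(1, 0)), 2 * log(2))
  # approaches zero as the prediction approaches the one-hot target
  expect_lt(cross_entropy(c(1 - 1e-9, 1e-9), c(1, 0)), 1e-7)
  # brute-force term-by-term evaluation
  cases <- eamreg:::with_seed(3L, lapply(1:20, function(i) {
    y1 <- runif(1, 0.01, 0.99)
    list(y = c(y1, 1 - y1), t = sample(c(0, 1)))
  }))
  for (cs in cases) {
    brute <- 0
    for (j in 1:2) {
      brute <- brute - (cs$t[j] * log(cs$y[j]) + (1 - cs$t[j]) * log(1 - cs$y[j]))
    }
    expect_equal(cross_entropy(cs$y, cs$t), brute, tolerance = 1e-12)
    expect_gte(cross_entropy(cs$y, cs$t), 0)
  }
})

test_that("training reaches zero error on separable features and is seeded", {
  d <- 20L
  n <- 12L
  labels <- rep(c(0L, 1L), each = n / 2)
  X <- eamreg:::with_seed(4L, {
    base <- matrix(rnorm(n * d, 0, 0.3), n, d)
    base[labels == 1L, 1:5] <- base[labels == 1L, 1:5] + 3
    base
  })
  cfg <- mlp_config(input_dim = d, hidden_dim = 16L, epochs = 300L, seed = 5L)
  w <- train_mlp(X, labels, cfg)
  preds <- vapply(seq_len(n), function(i) {
    mlp_forward(X[i, ], w, cfg)$predicted_class
  }, integer(1))
  expect_equal(preds, labels)

  # same seed, same final loss; loss decreased
  w2 <- train_mlp(X, labels, cfg)
  tr <- attr(w, "loss_trace")
  expect_identical(attr(w2, "loss_trace"), tr)
  expect_lt(tr[length(tr)], tr[1])

  # epochs = 0 returns the initialisation
  cfg0 <- mlp_config(input_dim = d, hidden_dim = 16L, epochs = 0L, seed = 5L)
  expect_identical(train_mlp(X, labels, cfg0), mlp_init(cfg0))

  expect_error(train_mlp(X, rep(1L, n), cfg), "single class")
  expect_error(train_mlp(X[1, , drop = FALSE], 1L, cfg), "at least 2")
})

test_that("the ensemble averages probabilities componentwise", {
  pu <- eamreg:::prediction(c(0.9, 0.1), "p1")
  pb <- eamreg:::prediction(c(0.1, 0.9), "p1")
  e <- ensemble_predict(pu, pb, weight = 0.5)
  expect_equal(e$probabilities, c(0.5, 0.5))
  expect_equal(e$predicted_class, 0L)  # tie rule

  # idempotence when both channels agree
  expect_equal(ensemble_predict(pu, pu)$probabilities, pu$probabilities)

  # random pairs: componentwise mean, still a probability vector
  pairs <- eamreg:::with_seed(6L, lapply(1:10, function(i) {
    a <- runif(1); b <- runif(1)
    list(u = eamreg:::prediction(c(a, 1 - a), "x"),
         b = eamreg:::prediction(c(b, 1 - b), "x"))
  }))
  for (pr in pairs) {
    e <- ensemble_predict(pr$u, pr$b, weight = 0.5)
    expect_equal(e$probabilities,
                 (pr$u$probabilities + pr$b$probabilities) / 2,
                 tolerance = 1e-12)
    expect_equal(sum(e$probabilities), 1, tolerance = 1e-12)
  }

  pz <- eamreg:::prediction(c(0.2, 0.8), "other")
  expect_error(ensemble_predict(pu, pz), "different patients")
})
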