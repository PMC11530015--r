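# Convolutional multi-label classifier.

zeroed_dense <- function(model) {
  model$params$theta[model$params$layout$dense$W] <- 0
  model$params$theta[model$params$layout$dense$b] <- 0
  model
}

test_that("forward pass maps any input into (0,1)^4; zero weights give 0.5", {
  cfg <- classifier_config(epochs = 1, seed = 3)
  set.seed(1)
  X <- matrix(rnorm(20 * 46, sd = 5), 20, 46)
  Y <- matrix(rbinom(80, 1, 0.5), 20, 4)
  model <- train_classifier(X, Y, cfg)
  p <- predict_proba(model, X)
  expect_true(all(p > 0 & p < 1))
  expect_equal(dim(p), c(20, 4))
  # all-zero weights and biases: sigmoid(0) = 0.5 for every output
  m0 <- model
  m0$params$theta[] <- 0
  expect_equal(unname(predict_proba(m0, X)), matrix(0.5, 20, 4))
  # shape validation
  expect_error(predict_proba(model, X[, 1:30]), "expected 46")
  expect_error(train_classifier(X[, 1:30], Y, cfg), "expected 46")
})

test_that("binary cross-entropy has its closed-form values", {
  expect_equal(bce_loss(0.5, 1), log(2))
  expect_equal(bce_loss(0.5, 0), log(2))
  # near-perfect predictions give near-zero loss; exact 0/1 are clamped
  expect_lt(bce_loss(c(1e-9, 1 - 1e-9), c(0, 1)), 1e-6)
  expect_true(is.finite(bce_loss(c(0, 1), c(0, 1))))
  # permutation invariance over samples
  set.seed(6)
  p <- matrix(runif(40), 10, 4)
  y <- matrix(rbinom(40, 1, 0.5), 10, 4)
  ord <- sample(10)
  expect_equal(bce_loss(p, y), bce_loss(p[ord, ], y[ord, ]))
})

test_that("a zero-initialized output layer starts at loss log 2", {
  cfg <- classifier_config(epochs = 1, seed = 8)
  set.seed(2)
  X <- matrix(rnorm(30 * 46), 30, 46)
  Y <- matrix(rbinom(120, 1, 0.5), 30, 4)
  model <- zeroed_dense(train_classifier(X, Y, cfg))
  p <- predict_proba(model, X)
  expect_equal(unname(p), matrix(0.5, 30, 4))
  expect_equal(bce_loss(p, Y), log(2))
})

test_that("thresholding is boundary-inclusive at 0.5", {
  expect_equal(unname(predict_labels(c(0.6, 0.4, 0.5, 0.1))), c(1, 0, 1, 0))
  expect_equal(unname(predict_labels(c(0, 0, 0, 0))), c(0, 0, 0, 0))
  expect_equal(unname(predict_labels(c(1, 1, 1, 1))), c(1, 1, 1, 1))
  m <- matrix(c(0.49, 0.51), 1)
  expect_equal(unname(predict_labels(cbind(m, m))[1, ]), c(0, 1, 0, 1))
  expect_error(predict_labels(c(0.5, 0.2, 1.4, 0)), "probabilities")
})

test_that("training is seed-deterministic and logs one loss per epoch", {
  set.seed(10)
  X <- matrix(rnorm(50 * 46), 50, 46)
  Y <- matrix(rbinom(200, 1, 0.4), 50, 4)
  cfg <- classifier_config(epochs = 7, seed = 21)
  m1 <- train_classifier(X, Y, cfg)
  m2 <- train_classifier(X, Y, cfg)
  expect_identical(m1$params$theta, m2$params$theta)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_length(m1$loss_history, 7)
  expect_identical(predict_proba(m1, X), predict_proba(m2, X))
})

test_that("loss decreases and a separable toy set is fit exactly", {
  # distinct strong feature patterns per label combination
  set.seed(33)
  cats <- rep(c(1, 2, 5, 11), each = 5)
  X <- matrix(rnorm(20 * 46, sd = 0.05), 20, 46)
  for (i in seq_len(20)) X[i, cats[i] * 3 + (0:2)] <- 1
  Y <- onehot_label(cats)
  model <- train_classifier(X, Y, classifier_config(epochs = 120, seed = 2,
                                                    batch_size = 10))
  expect_lt(model$loss_history[50], model$loss_history[1])
  pred <- predict_labels(predict_proba(model, X))
  m <- multilabel_metrics(Y, pred)
  expect_equal(m$absolute_true, 1)
})
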