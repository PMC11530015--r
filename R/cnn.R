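# Convolutional multi-label classifier.
#
# A 46-dimensional propensity feature vector is treated as a 1-channel,
# length-46 signal and passed through four (convolution -> ReLU -> max-pool)
# blocks followed by one fully connected layer with sigmoid outputs, one per
# modification type. Training minimizes binary cross-entropy with the Adam
# optimizer. The forward/backward passes are compiled (src/cnn_kernels.cpp);
# parameters live in one flat vector whose layout is defined by
# .param_layout() and mirrored by the C++ side.

#' Classifier configuration
#'
#' The architecture is fixed at four convolution blocks, four max-pool layers
#' and one fully connected output layer; channel widths, kernel size, pooling
#' and the optimization schedule are configurable. With the defaults the
#' signal length shrinks 46 -> 23 -> 11 -> 5 -> 2, giving a 256-unit flatten
#' before the 4-unit sigmoid output.
#'
#' @param channels Integer vector of 4 convolution channel widths.
#' @param kernel Convolution kernel width (odd; default 3, padding
#'   `(kernel - 1) / 2` keeps the length).
#' @param pool Max-pool width and stride (default 2; remainder positions are
#'   dropped).
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @param threshold Decision threshold on the output probabilities
#'   (default 0.5, boundary inclusive).
#' @param input_len Input feature length (46 for MLPSTAAP features).
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(channels = c(16L, 32L, 64L, 128L), kernel = 3L,
                              pool = 2L, lr = 1e-3, epochs = 100L,
                              batch_size = 64L, seed = 1L, threshold = 0.5,
                              input_len = 46L) {
  stopifnot(length(channels) == 4L, kernel %% 2L == 1L, pool >= 1L,
            threshold > 0, threshold < 1, epochs >= 1L, batch_size >= 1L)
  lens <- integer(5L)
  lens[1L] <- as.integer(input_len)
  for (l in 1:4) lens[l + 1L] <- lens[l] %/% as.integer(pool)
  if (lens[5L] < 1L) stop("input_len ", input_len, " too short for 4 pool layers")
  structure(list(channels = as.integer(channels), kernel = as.integer(kernel),
                 pool = as.integer(pool), lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), threshold = threshold,
                 input_len = as.integer(input_len), lengths = lens,
                 flat_dim = lens[5L] * as.integer(channels[4L])),
            class = "classifier_config")
}

# Flat parameter layout: per conv block W (kernel*c_in x c_out) then b,
# finally dense W (flat_dim x 4) then b. Must match unpack() in
# src/cnn_kernels.cpp.
.param_layout <- function(config) {
  c_in <- c(1L, config$channels[1:3])
  off <- 0L
  conv <- vector("list", 4L)
  for (l in 1:4) {
    nW <- config$kernel * c_in[l] * config$channels[l]
    nb <- config$channels[l]
    conv[[l]] <- list(W = off + seq_len(nW), b = off + nW + seq_len(nb))
    off <- off + nW + nb
  }
  nW <- config$flat_dim * 4L
  dense <- list(W = off + seq_len(nW), b = off + nW + seq_len(4L))
  list(conv = conv, dense = dense, total = off + nW + 4L)
}

# He-normal conv weights, Glorot dense; biases zero. Uses the current RNG.
.init_params <- function(config) {
  layout <- .param_layout(config)
  theta <- numeric(layout$total)
  c_in <- c(1L, config$channels[1:3])
  for (l in 1:4) {
    fan_in <- config$kernel * c_in[l]
    idx <- layout$conv[[l]]$W
    theta[idx] <- stats::rnorm(length(idx), sd = sqrt(2 / fan_in))
  }
  idx <- layout$dense$W
  theta[idx] <- stats::rnorm(length(idx), sd = sqrt(2 / (config$flat_dim + 4L)))
  theta
}

.forward_prob <- function(theta, X, config) {
  .cnn_forward_cpp(theta, X, config$channels, config$kernel, config$pool,
                   config$input_len)
}

#' Binary cross-entropy loss
#'
#' Mean over samples and labels of `-[y log(p) + (1 - y) log(1 - p)]`.
#' Probabilities at exactly 0 or 1 are clamped to `[epsilon, 1 - epsilon]`
#' for numerical safety.
#'
#' @param predicted n x 4 matrix (or length-4 vector) of probabilities.
#' @param target Matching matrix/vector of 0/1 labels.
#' @param epsilon Clamping constant (default 1e-7).
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' bce_loss(0.5, 1)  # log(2)
bce_loss <- function(predicted, target, epsilon = 1e-7) {
  p <- pmin(pmax(predicted, epsilon), 1 - epsilon)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

#' Train the convolutional multi-label classifier
#'
#' Mini-batch gradient descent (Adam) on the binary cross-entropy loss.
#' Weight initialization and batch shuffling are driven by `config$seed`, so
#' training is deterministic on a fixed platform.
#'
#' @param features n x 46 feature matrix.
#' @param labels n x 4 binary label matrix.
#' @param config [classifier_config()].
#' @return Object of class `multilabel_cnn`: list with `params` (flat weight
#'   vector plus layout), `config` and `loss_history` (mean epoch loss,
#'   length `epochs`).
#' @export
train_classifier <- function(features, labels, config = classifier_config()) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (ncol(features) != config$input_len) {
    stop("expected ", config$input_len, " features, got ", ncol(features))
  }
  n <- nrow(features)
  if (n == 0L) stop("empty training set")
  stopifnot(nrow(labels) == n, ncol(labels) == 4L)
  rng <- .local_rng(config$seed)
  on.exit(rng())
  theta <- .init_params(config)
  m <- v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  t_step <- 0L
  loss_history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq.int(1L, n, by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      step <- .cnn_train_step_cpp(theta, features[idx, , drop = FALSE],
                                  labels[idx, , drop = FALSE],
                                  config$channels, config$kernel,
                                  config$pool, config$input_len)
      if (!is.finite(step$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             " (batch starting at ", s, "); check inputs / learning rate")
      }
      epoch_loss <- epoch_loss + step$loss * length(idx)
      g <- as.numeric(step$grad)
      t_step <- t_step + 1L
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      theta <- theta - config$lr * (m / (1 - beta1^t_step)) /
        (sqrt(v / (1 - beta2^t_step)) + adam_eps)
    }
    loss_history[epoch] <- epoch_loss / n
  }
  structure(list(params = list(theta = theta, layout = .param_layout(config)),
                 config = config, loss_history = loss_history),
            class = "multilabel_cnn")
}

#' @export
print.multilabel_cnn <- function(x, ...) {
  cat("multilabel_cnn: channels", paste(x$config$channels, collapse = "-"),
      "| kernel", x$config$kernel, "| epochs trained",
      length(x$loss_history), "\n")
  if (length(x$loss_history) > 0L) {
    cat("final mean epoch loss:", format(utils::tail(x$loss_history, 1)), "\n")
  }
  invisible(x)
}

#' Predict modification probabilities
#'
#' @param model `multilabel_cnn`.
#' @param features n x 46 feature matrix.
#' @param chunk Forward-pass batch size (memory bound only).
#' @return n x 4 matrix of probabilities in (0, 1), columns A, C, M, S.
#' @export
predict_proba <- function(model, features, chunk = 2048L) {
  features <- as.matrix(features)
  if (ncol(features) != model$config$input_len) {
    stop("expected ", model$config$input_len, " features, got ", ncol(features))
  }
  n <- nrow(features)
  out <- matrix(NA_real_, n, 4L, dimnames = list(NULL, MOD_LETTERS))
  for (s in seq.int(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    out[idx, ] <- .forward_prob(model$params$theta,
                                features[idx, , drop = FALSE], model$config)
  }
  out
}

#' Threshold probabilities into binary label flags
#'
#' A flag is set iff its probability is greater than or equal to the
#' threshold (boundary inclusive). The all-zero pattern is a valid outcome
#' meaning "no modification predicted".
#'
#' @param probabilities n x 4 matrix (or length-4 vector) of values in
#'   `[0, 1]`.
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return Matching matrix/vector of 0/1 flags.
#' @export
#' @examples
#' predict_labels(c(0.6, 0.4, 0.5, 0.1))  # 1 0 1 0
predict_labels <- function(probabilities, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1,
            all(probabilities >= 0), all(probabilities <= 1))
  flags <- ifelse(probabilities >= threshold, 1L, 0L)
  if (is.matrix(probabilities)) colnames(flags) <- MOD_LETTERS
  flags
}
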