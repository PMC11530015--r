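# Shared fixtures and independent oracles, all built in code.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Random 49-mer window with central K (optionally over a reduced alphabet).
random_window <- function(alphabet = AA20) {
  ctx <- sample(alphabet, 48, replace = TRUE)
  paste0(paste(ctx[1:24], collapse = ""), "K", paste(ctx[25:48], collapse = ""))
}

# Window whose 48-residue context is given explicitly.
window_from_context <- function(context) {
  stopifnot(nchar(context) == 48)
  paste0(substr(context, 1, 24), "K", substr(context, 25, 48))
}

# Random truth/prediction pair over the 11 admissible categories; predictions
# are arbitrary 4-bit patterns (possibly empty).
random_eval_case <- function(n) {
  cats <- sample(1:11, n, replace = TRUE)
  truth <- onehot_label(cats)
  if (n == 1) truth <- matrix(truth, nrow = 1)
  pred <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
  list(categories = cats, truth = truth, pred = pred)
}

# Brute-force set-arithmetic oracle for the five multi-label metrics,
# deliberately written with explicit per-sample set operations.
oracle_metrics <- function(truth, pred) {
  n <- nrow(truth)
  aim <- cov <- acc <- abt <- abf <- numeric(n)
  for (i in seq_len(n)) {
    Y <- which(truth[i, ] == 1)
    Ys <- which(pred[i, ] == 1)
    inter <- length(intersect(Y, Ys))
    uni <- length(union(Y, Ys))
    aim[i] <- if (length(Ys) == 0) 0 else inter / length(Ys)
    cov[i] <- inter / length(Y)
    acc[i] <- if (uni == 0) 0 else inter / uni
    abt[i] <- as.numeric(setequal(Y, Ys))
    abf[i] <- (uni - inter) / 4
  }
  c(aiming = mean(aim), coverage = mean(cov), accuracy = mean(acc),
    absolute_true = mean(abt), absolute_false = mean(abf))
}

# Well-separated Gaussian blobs for clustering tests.
make_blobs <- function(n_per, centers, spread = 0.2) {
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = spread), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  pts
}

# Small all-11-category synthetic window table for encoder/CV tests.
small_window_table <- function(n_per = 10, seed = 1, prob = 1) {
  motifs <- lapply(1:11, function(t) {
    list(list(position = 4L * (t - 1L) + 3L,
              triad = strrep(c("A", "C", "D", "E", "F", "G", "H", "I", "L",
                               "M", "N")[t], 3L),
              prob = prob))
  })
  generate_windows(synthetic_spec(rep(n_per, 11), motifs, seed = seed))
}
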