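# Set-based multi-label evaluation (Chou's five metrics).
#
# For each sample, Y is the true label set and Y* the predicted set over the
# M = 4 modification types:
#   Aiming          mean |Y n Y*| / |Y*|     (precision-like)
#   Coverage        mean |Y n Y*| / |Y|      (recall-like)
#   Accuracy        mean |Y n Y*| / |Y u Y*| (Jaccard)
#   Absolute-True   fraction of exact matches
#   Absolute-False  mean (|Y u Y*| - |Y n Y*|) / M
# A sample with an empty predicted set contributes 0 to Aiming (the formula's
# denominator would be 0; maximal penalty is applied) and its count is
# reported.

#' Compute the five multi-label metrics
#'
#' @param truth n x 4 binary matrix of true labels (each row non-empty).
#' @param predicted n x 4 binary matrix of predicted flags (all-zero rows
#'   allowed: "no modification predicted").
#' @return Object of class `metrics_report`: list with `aiming`, `coverage`,
#'   `accuracy`, `absolute_true`, `absolute_false` (all in `[0, 1]`), `n`,
#'   `M` and `n_empty_predictions`.
#' @export
multilabel_metrics <- function(truth, predicted) {
  truth <- as.matrix(truth)
  predicted <- as.matrix(predicted)
  stopifnot(nrow(truth) == nrow(predicted), ncol(truth) == 4L,
            ncol(predicted) == 4L, nrow(truth) > 0L)
  if (any(rowSums(truth) == 0L)) stop("true label sets must be non-empty")
  M <- 4L
  inter <- rowSums(truth == 1L & predicted == 1L)
  size_true <- rowSums(truth)
  size_pred <- rowSums(predicted)
  size_union <- size_true + size_pred - inter
  empty_pred <- size_pred == 0L
  aiming_terms <- ifelse(empty_pred, 0, inter / pmax(size_pred, 1L))
  exact <- rowSums(truth == predicted) == M
  rep <- list(
    aiming = mean(aiming_terms),
    coverage = mean(inter / size_true),
    accuracy = mean(inter / size_union),
    absolute_true = mean(exact),
    absolute_false = mean((size_union - inter) / M),
    n = nrow(truth),
    M = M,
    n_empty_predictions = sum(empty_pred)
  )
  stopifnot(rep$absolute_true <= rep$accuracy + 1e-12)
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f", 100 * v)
  cat("Multi-label metrics (n = ", x$n, ", M = ", x$M, "):\n", sep = "")
  cat("  Aiming         ", pct(x$aiming), "%\n", sep = "")
  cat("  Coverage       ", pct(x$coverage), "%\n", sep = "")
  cat("  Accuracy       ", pct(x$accuracy), "%\n", sep = "")
  cat("  Absolute-True  ", pct(x$absolute_true), "%\n", sep = "")
  cat("  Absolute-False ", pct(x$absolute_false), "%\n", sep = "")
  if (x$n_empty_predictions > 0L) {
    cat("  (", x$n_empty_predictions, " empty prediction(s))\n", sep = "")
  }
  invisible(x)
}

#' Per-category exact-match rates
#'
#' For each of the 11 categories, the fraction of its samples whose predicted
#' flag vector equals the true vector exactly. Categories absent from the
#' evaluation set are reported as NA, not 0.
#'
#' @param categories Integer vector of true category ids (1..11).
#' @param truth,predicted n x 4 binary matrices.
#' @return Named numeric vector of length 11 (names from
#'   [category_names()]).
#' @export
per_category_absolute_true <- function(categories, truth, predicted) {
  truth <- as.matrix(truth)
  predicted <- as.matrix(predicted)
  stopifnot(length(categories) == nrow(truth))
  exact <- rowSums(truth == predicted) == 4L
  out <- rep(NA_real_, 11L)
  for (t in 1:11) {
    in_cat <- categories == t
    if (any(in_cat)) out[t] <- mean(exact[in_cat])
  }
  stats::setNames(out, category_names())
}
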