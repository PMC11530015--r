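# Stratified cross-validation and the undersampling-ratio sweep.
#
# Everything fitted from data — the propensity matrices, the undersampled
# prototypes and the classifier — is computed inside each training fold only,
# so no information from a held-out fold leaks into the model evaluated on it.

# Category-stratified fold labels, seed-deterministic. Categories with fewer
# members than folds are spread best-effort with a warning.
.fold_assignment <- function(categories, folds, seed) {
  rng <- .local_rng(seed)
  on.exit(rng())
  fold_of <- integer(length(categories))
  for (t in sort(unique(categories))) {
    idx <- which(categories == t)
    if (length(idx) < folds) {
      warning("category ", t, " has ", length(idx), " member(s) for ", folds,
              "-fold CV; stratified best-effort", call. = FALSE)
    }
    fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  fold_of
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Folds are stratified by category. Per fold: the propensity model is fitted
#' on the training folds, both splits are encoded, the majority class of the
#' training folds is undersampled to `ratio`, the classifier is trained, and
#' the held-out fold is scored.
#'
#' @param windows Window table with all 11 categories.
#' @param folds Number of folds (default 5).
#' @param ratio Undersampling ratio in (0, 1]; 1 disables undersampling.
#' @param majority_category Category to undersample; NULL (default) picks the
#'   largest category of each training split.
#' @param batch_size,max_iter Mini-batch k-means parameters.
#' @param config [classifier_config()]; its seed is re-derived per fold from
#'   `seed`.
#' @param seed Global seed; fold assignment and all stage seeds derive from
#'   it.
#' @return List with `mean` (metric means across folds plus
#'   `per_category_absolute_true`), `folds` (per-fold `metrics_report`s and
#'   per-category tables) and `fold_assignment`.
#' @export
cross_validate <- function(windows, folds = 5L, ratio = 0.1,
                           majority_category = NULL, batch_size = 1024L,
                           max_iter = 100L, config = classifier_config(),
                           seed = 1L) {
  if (folds < 2L) stop("folds must be >= 2")
  fold_of <- .fold_assignment(windows$category, folds, .stage_seed(seed, 1L))
  fold_reports <- vector("list", folds)
  fold_cat <- matrix(NA_real_, nrow = folds, ncol = 11L,
                     dimnames = list(NULL, category_names()))
  for (f in seq_len(folds)) {
    train_w <- windows[fold_of != f, , drop = FALSE]
    test_w <- windows[fold_of == f, , drop = FALSE]
    model <- fit_propensity(train_w)
    train_set <- sample_set(encode_windows(train_w, model),
                            onehot_label(train_w$category),
                            train_w$category)
    maj <- majority_category
    if (is.null(maj)) maj <- as.integer(which.max(tabulate(train_w$category, 11L)))
    if (ratio < 1) {
      train_set <- cluster_centroids_undersample(
        train_set, majority_category = maj, ratio = ratio,
        batch_size = batch_size, max_iter = max_iter,
        seed = .stage_seed(seed, 100L + f))
    }
    cfg <- config
    cfg$seed <- .stage_seed(seed, 200L + f)
    cls <- train_classifier(train_set$features, train_set$labels, cfg)
    prob <- predict_proba(cls, encode_windows(test_w, model))
    pred <- predict_labels(prob, cfg$threshold)
    truth <- onehot_label(test_w$category)
    fold_reports[[f]] <- multilabel_metrics(truth, pred)
    fold_cat[f, ] <- per_category_absolute_true(test_w$category, truth, pred)
  }
  metric_names <- c("aiming", "coverage", "accuracy", "absolute_true",
                    "absolute_false")
  means <- vapply(metric_names, function(m) {
    mean(vapply(fold_reports, `[[`, numeric(1L), m))
  }, numeric(1L))
  list(mean = c(as.list(means),
                list(per_category_absolute_true =
                       colMeans(fold_cat, na.rm = TRUE))),
       folds = list(reports = fold_reports,
                    per_category_absolute_true = fold_cat),
       fold_assignment = fold_of)
}

#' Sweep the undersampling ratio
#'
#' Runs [cross_validate()] once per ratio with a shared seed (identical fold
#' assignment across ratios) and collects the per-category exact-match rates.
#'
#' @param windows Window table.
#' @param ratios Numeric vector of ratios in (0, 1].
#' @param ... Passed to [cross_validate()].
#' @param seed Global seed shared by all ratios.
#' @return data.frame with one row per ratio: column `ratio` plus the 11
#'   category columns (A, C, M, S, AC, AM, AS, CM, ACM, ACS, ACMS) holding
#'   mean per-category Absolute-True across folds.
#' @export
ratio_sweep <- function(windows, ratios, ..., seed = 1L) {
  stopifnot(length(ratios) >= 1L, all(ratios > 0), all(ratios <= 1))
  rows <- lapply(ratios, function(r) {
    cv <- cross_validate(windows, ratio = r, ..., seed = seed)
    c(ratio = r, cv$mean$per_category_absolute_true)
  })
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  rownames(out) <- NULL
  out
}
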