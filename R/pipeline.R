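# End-to-end pipeline: FASTA + annotations -> trained predictor artifact,
# and prediction/evaluation on new sites.

#' Fit the full predictor from FASTA + annotations
#'
#' Runs windowing, deduplication, category filtering, the stratified
#' train/test split, propensity fitting (training split only), encoding,
#' majority-class undersampling and classifier training. All stage seeds
#' derive from the single `seed` by fixed offsets.
#'
#' @param fasta_path Protein FASTA file.
#' @param annotations_path Site-annotation TSV (protein_id, position, mods).
#' @param train_fraction Train split fraction (default 0.7).
#' @param min_per_category Category floor applied before splitting
#'   (default 60).
#' @param ratio Undersampling ratio in (0, 1] (default 0.1).
#' @param majority_category Category to undersample; NULL picks the largest
#'   training category.
#' @param batch_size,max_iter Mini-batch k-means parameters.
#' @param config [classifier_config()]; its seed is re-derived from `seed`.
#' @param seed Global seed.
#' @return Object of class `lysmod_model`: list with `propensity`,
#'   `classifier`, `threshold`, the held-out `test_windows`, `train_windows`,
#'   and a `provenance` record (config echo, stage seeds, counts).
#' @export
fit_pipeline <- function(fasta_path, annotations_path, train_fraction = 0.7,
                         min_per_category = 60L, ratio = 0.1,
                         majority_category = NULL, batch_size = 1024L,
                         max_iter = 100L, config = classifier_config(),
                         seed = 1L) {
  sequences <- read_fasta(fasta_path)
  annotations <- read_annotations(annotations_path)
  windows <- build_windows(sequences, annotations)
  windows <- deduplicate(windows)
  windows <- filter_categories(windows, min_per_category)
  if (nrow(windows) == 0L) stop("no usable windows after filtering")
  split_seed <- .stage_seed(seed, 1L)
  split <- split_dataset(windows, train_fraction, seed = split_seed)
  propensity <- fit_propensity(split$train)
  train_set <- sample_set(encode_windows(split$train, propensity),
                          onehot_label(split$train$category),
                          split$train$category)
  maj <- majority_category
  if (is.null(maj)) {
    maj <- as.integer(which.max(tabulate(split$train$category, 11L)))
  }
  sampler_seed <- .stage_seed(seed, 2L)
  if (ratio < 1) {
    train_set <- cluster_centroids_undersample(
      train_set, majority_category = maj, ratio = ratio,
      batch_size = batch_size, max_iter = max_iter, seed = sampler_seed)
  }
  cfg <- config
  cfg$seed <- .stage_seed(seed, 3L)
  classifier <- train_classifier(train_set$features, train_set$labels, cfg)
  structure(
    list(propensity = propensity,
         classifier = classifier,
         threshold = cfg$threshold,
         train_windows = split$train,
         test_windows = split$test,
         provenance = list(
           seed = as.integer(seed),
           stage_seeds = list(split = split_seed, sampler = sampler_seed,
                              classifier = cfg$seed),
           train_fraction = train_fraction,
           min_per_category = as.integer(min_per_category),
           ratio = ratio, majority_category = maj,
           batch_size = as.integer(batch_size),
           max_iter = as.integer(max_iter),
           sampler_log = attr(train_set, "sampler_log"),
           n_windows = nrow(windows),
           n_train = nrow(split$train), n_test = nrow(split$test),
           encoder_fingerprint = .propensity_fingerprint(propensity),
           fitted_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    class = "lysmod_model")
}

# Cheap content fingerprint tying classifier artifacts to their encoder.
.propensity_fingerprint <- function(model) {
  m <- model$F_mlpstaap
  sprintf("%dx%d:%.12e:%.12e", nrow(m), ncol(m), sum(m), sum(abs(m)))
}

#' @export
print.lysmod_model <- function(x, ...) {
  cat("lysmod_model\n")
  cat("  trained on ", x$provenance$n_train, " windows (",
      x$provenance$n_test, " held out), undersampling ratio ",
      x$provenance$ratio, "\n", sep = "")
  print(x$classifier)
  invisible(x)
}

#' Save / load a fitted model artifact
#'
#' The artifact bundles the propensity matrices, classifier weights, config
#' and provenance (including the encoder fingerprint), so predictions are
#' reproducible end-to-end.
#'
#' @param model `lysmod_model`.
#' @param path Artifact path (RDS container).
#' @return `path` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lysmod_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "lysmod_model"))
  model
}

#' Predict modifications at queried lysine sites
#'
#' @param model `lysmod_model`.
#' @param sequences Named character vector of protein sequences.
#' @param sites data.frame with columns protein_id and position; an optional
#'   `mods` column (annotation tokens) adds a Targets column with the true
#'   label string.
#' @return data.frame with one row per queried site: Sample, protein_id,
#'   position, the four per-type probabilities (prob_A..prob_S), the binary
#'   flags, Results (decoded predicted label string; empty when no
#'   modification is predicted), optionally Targets, and an `error` column
#'   (NA on success; failed rows carry the message and NA predictions while
#'   the run continues).
#' @export
predict_sites <- function(model, sequences, sites) {
  stopifnot(inherits(model, "lysmod_model"))
  n <- nrow(sites)
  res <- data.frame(Sample = seq_len(n),
                    protein_id = as.character(sites$protein_id),
                    position = as.integer(sites$position),
                    prob_A = rep(NA_real_, n), prob_C = rep(NA_real_, n),
                    prob_M = rep(NA_real_, n), prob_S = rep(NA_real_, n),
                    A = rep(NA_integer_, n), C = rep(NA_integer_, n),
                    M = rep(NA_integer_, n), S = rep(NA_integer_, n),
                    Results = rep(NA_character_, n),
                    error = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  windows <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    pid <- res$protein_id[i]
    if (!pid %in% names(sequences)) {
      res$error[i] <- paste0("unknown protein ", pid)
      next
    }
    windows[i] <- tryCatch(
      extract_window(sequences[[pid]], res$position[i], pid),
      error = function(e) {
        res$error[i] <<- conditionMessage(e)
        NA_character_
      })
  }
  ok <- !is.na(windows)
  if (any(ok)) {
    feat <- encode_windows(windows[ok], model$propensity)
    prob <- predict_proba(model$classifier, feat)
    flags <- predict_labels(prob, model$threshold)
    res[ok, c("prob_A", "prob_C", "prob_M", "prob_S")] <- prob
    res[ok, MOD_LETTERS] <- flags
    res$Results[ok] <- decode_flags(flags)
  }
  if (!is.null(sites$mods)) {
    res$Targets <- vapply(strsplit(as.character(sites$mods), ","), function(m) {
      m <- trimws(m[nzchar(trimws(m))])
      cat_id <- tryCatch(assign_category(m), error = function(e) NA_integer_)
      if (is.na(cat_id)) NA_character_ else decode_flags(onehot_label(cat_id))
    }, character(1L))
  }
  res
}

#' Evaluate a fitted model on labeled windows
#'
#' @param model `lysmod_model`.
#' @param windows Window table with true categories; defaults to the model's
#'   held-out test split.
#' @return List with `metrics` (a `metrics_report`) and
#'   `per_category_absolute_true`.
#' @export
evaluate_model <- function(model, windows = model$test_windows) {
  stopifnot(inherits(model, "lysmod_model"), nrow(windows) > 0L)
  feat <- encode_windows(windows, model$propensity)
  prob <- predict_proba(model$classifier, feat)
  pred <- predict_labels(prob, model$threshold)
  truth <- onehot_label(windows$category)
  list(metrics = multilabel_metrics(truth, pred),
       per_category_absolute_true =
         per_category_absolute_true(windows$category, truth, pred))
}
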