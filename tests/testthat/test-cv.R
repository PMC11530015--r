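# Cross-validation harness and ratio sweep.

quick_cfg <- classifier_config(epochs = 8L, seed = 1L)

test_that("folds stratify by category, partition the data and are seeded", {
  win <- small_window_table(n_per = 10, seed = 41)
  f1 <- lysmod:::.fold_assignment(win$category, 5, seed = 7)
  f2 <- lysmod:::.fold_assignment(win$category, 5, seed = 7)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:5)
  # each category splits 2-2-2-2-2
  for (t in 1:11) {
    expect_equal(as.integer(table(f1[win$category == t])), rep(2, 5))
  }
  expect_warning(lysmod:::.fold_assignment(rep(1:2, c(3, 20)), 5, 1),
                 "best-effort")
})

test_that("cross-validation reports per-fold and mean metrics reproducibly", {
  win <- small_window_table(n_per = 12, seed = 43)
  cv <- cross_validate(win, folds = 3, ratio = 0.5, config = quick_cfg,
                       seed = 11)
  expect_length(cv$folds$reports, 3)
  expect_equal(dim(cv$folds$per_category_absolute_true), c(3, 11))
  for (m in c("aiming", "coverage", "accuracy", "absolute_true")) {
    expect_gte(cv$mean[[m]], 0)
    expect_lte(cv$mean[[m]], 1)
  }
  expect_equal(cv$mean$absolute_true,
               mean(vapply(cv$folds$reports, `[[`, numeric(1),
                           "absolute_true")))
  # every sample held out exactly once
  expect_equal(sort(unique(cv$fold_assignment)), 1:3)
  expect_equal(sum(vapply(cv$folds$reports, `[[`, numeric(1), "n")),
               nrow(win))
  cv2 <- cross_validate(win, folds = 3, ratio = 0.5, config = quick_cfg,
                        seed = 11)
  expect_identical(cv$mean, cv2$mean)
  expect_error(cross_validate(win, folds = 1), "folds")
})

test_that("a single-ratio sweep equals one cross-validation run", {
  win <- small_window_table(n_per = 12, seed = 47)
  sweep_tab <- ratio_sweep(win, 0.5, folds = 3, config = quick_cfg, seed = 13)
  cv <- cross_validate(win, folds = 3, ratio = 0.5, config = quick_cfg,
                       seed = 13)
  expect_equal(dim(sweep_tab), c(1, 12))
  expect_equal(unlist(sweep_tab[1, -1]), cv$mean$per_category_absolute_true)
  expect_equal(names(sweep_tab),
               c("ratio", "A", "C", "M", "S", "AC", "AM", "AS", "CM", "ACM",
                 "ACS", "ACMS"))
})

test_that("with no planted signal the classifier falls back to the majority", {
  counts <- c(120, rep(8, 10))
  motifs <- lapply(1:11, function(t) {
    list(list(position = 4L * (t - 1L) + 3L, triad = "AAA", prob = 0))
  })
  win <- generate_windows(synthetic_spec(counts, motifs, seed = 53))
  sp <- split_dataset(win, 0.7, seed = 3)
  pm <- fit_propensity(sp$train)
  cls <- train_classifier(encode_windows(sp$train, pm),
                          onehot_label(sp$train$category),
                          classifier_config(epochs = 30, seed = 5))
  pred <- predict_labels(predict_proba(cls, encode_windows(sp$test, pm)))
  m <- multilabel_metrics(onehot_label(sp$test$category), pred)
  maj_frac <- mean(sp$test$category == 1)
  expect_lt(abs(m$absolute_true - maj_frac), 0.1)
})
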