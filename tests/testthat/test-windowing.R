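# Window extraction, category assignment, labels, dedup, split.

test_that("window extraction covers +/-24 flanks and pads termini with X", {
  seq100 <- paste(c(rep("A", 49), "K", rep("L", 50)), collapse = "")
  w <- extract_window(seq100, 50)
  expect_equal(nchar(w), 49)
  expect_equal(w, substr(seq100, 26, 74))
  expect_equal(substr(w, 25, 25), "K")

  # K at position 1: 24 leading X then 25 true residues
  seqK1 <- paste(c("K", rep("R", 40)), collapse = "")
  w1 <- extract_window(seqK1, 1)
  expect_equal(substr(w1, 1, 24), strrep("X", 24))
  expect_equal(substr(w1, 25, 49), substr(seqK1, 1, 25))

  # K at the C-terminus pads on the right
  seqKend <- paste(c(rep("G", 30), "K"), collapse = "")
  wend <- extract_window(seqKend, 31)
  expect_equal(substr(wend, 26, 49), strrep("X", 24))
})

test_that("non-lysine positions are rejected with protein and position named", {
  expect_error(extract_window("AAAKAAA", 2, "P1"),
               "position 2 of protein P1")
  expect_error(extract_window("AAAKAAA", 99, "P1"), "outside")
})

test_that("non-standard residues are normalized to X with a warning", {
  s <- paste(c(rep("A", 24), "K", "U", rep("A", 23)), collapse = "")
  expect_warning(w <- extract_window(s, 25), "non-standard")
  expect_equal(substr(w, 26, 26), "X")
})

test_that("the 11 admissible combinations map bijectively, the 4 others fail", {
  expect_equal(assign_category("acetyl"), 1)
  expect_equal(assign_category(c("acetyl", "crotonyl")), 5)
  expect_equal(assign_category(c("acetyl", "crotonyl", "methyl", "succinyl")), 11)
  # round trip over all categories
  for (t in 1:11) {
    expect_equal(assign_category(category_mods(t)), t)
    expect_equal(flags_to_category(onehot_label(t)), t)
  }
  inadmissible <- list(c("crotonyl", "succinyl"),
                       c("methyl", "succinyl"),
                       c("acetyl", "methyl", "succinyl"),
                       c("crotonyl", "methyl", "succinyl"))
  for (mods in inadmissible) {
    expect_error(assign_category(mods), "unsupported combination")
  }
  expect_error(assign_category("phospho"), "unknown")
  expect_error(assign_category(character(0)), "empty")
})

test_that("one-hot labels match the category patterns", {
  expect_equal(unname(onehot_label(1)), c(1, 0, 0, 0))
  expect_equal(unname(onehot_label(5)), c(1, 1, 0, 0))
  expect_equal(unname(onehot_label(11)), c(1, 1, 1, 1))
  expect_equal(decode_flags(onehot_label(8)), "CM")
  expect_equal(decode_flags(c(0, 0, 0, 0)), "")
})

test_that("deduplication keeps one window per string and unions categories", {
  w <- random_window()
  tab <- data.frame(protein_id = c("p1", "p2", "p3"), center_pos = 25L,
                    residues = c(w, w, random_window()),
                    category = c(1L, 1L, 3L), stringsAsFactors = FALSE)
  out <- deduplicate(tab)
  expect_equal(nrow(out), 2)

  # categories 1 (acetyl) + 2 (crotonyl) union to 5 (acetyl+crotonyl)
  tab2 <- tab
  tab2$category <- c(1L, 2L, 3L)
  expect_warning(out2 <- deduplicate(tab2), "conflicting")
  expect_equal(out2$category[out2$residues == w], 5)

  # methyl + succinyl union is inadmissible -> dropped
  tab3 <- tab
  tab3$category <- c(3L, 4L, 1L)
  expect_warning(out3 <- deduplicate(tab3), "inadmissible")
  expect_false(w %in% out3$residues)

  empty <- tab[0, ]
  expect_equal(nrow(deduplicate(empty)), 0)
})

test_that("stratified split partitions the data reproducibly", {
  set.seed(99)
  tab <- data.frame(protein_id = sprintf("p%03d", 1:30), center_pos = 25L,
                    residues = replicate(30, random_window()),
                    category = rep(c(1L, 2L, 3L), times = c(10, 12, 8)),
                    stringsAsFactors = FALSE)
  sp <- split_dataset(tab, 0.7, seed = 5)
  expect_equal(sum(sp$train$category == 1), 7)
  expect_equal(sum(sp$test$category == 1), 3)
  # partition: union equals input, intersection empty
  all_res <- sort(c(sp$train$residues, sp$test$residues))
  expect_equal(all_res, sort(tab$residues))
  expect_length(intersect(sp$train$residues, sp$test$residues), 0)
  # determinism
  sp2 <- split_dataset(tab, 0.7, seed = 5)
  expect_identical(sp$train$residues, sp2$train$residues)
  # singleton category goes to train with a warning
  tab$category[1] <- 7L
  expect_warning(sp3 <- split_dataset(tab, 0.7, seed = 5), "category 7")
  expect_true(tab$residues[1] %in% sp3$train$residues)
})

test_that("annotation reader demands the documented columns", {
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(protein_id = "p", pos = 1), bad, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  expect_error(read_annotations(bad), "position")
  on.exit(unlink(bad))
})

test_that("window tables round-trip through TSV", {
  tab <- small_window_table(n_per = 2, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_windows(tab, path)
  back <- read_windows(path)
  expect_equal(back, tab)
  unlink(path)
})
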