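# Propensity encoder: row indexing, frequency matrices, fitting, encoding.

test_that("triad row index follows the positional formula and is a bijection", {
  expect_equal(triad_row_index("AGA"), 101)
  expect_equal(triad_row_index("GAT"), 2017)
  expect_equal(triad_row_index("AAA"), 1)
  expect_equal(triad_row_index("YYY"), 8000)
  # exhaustive bijection over all 20^3 triads
  all_triads <- do.call(paste0, expand.grid(AA20, AA20, AA20,
                                            stringsAsFactors = FALSE))
  expect_equal(sort(triad_row_index(all_triads)), 1:8000)
  # padding and unknown letters have no row
  expect_true(is.na(triad_row_index("AXA")))
  expect_true(is.na(triad_row_index("XAA")))
})

test_that("context drops exactly the central lysine", {
  w <- window_from_context(strrep("A", 48))
  expect_equal(context_of(w), strrep("A", 48))
  ctx <- paste(sample(AA20, 48, replace = TRUE), collapse = "")
  w2 <- window_from_context(ctx)
  expect_equal(nchar(context_of(w2)), 48)
  expect_equal(context_of(w2), ctx)
})

test_that("frequency matrix counts triads per position", {
  set.seed(11)
  ctx <- paste(sample(AA20, 48, replace = TRUE), collapse = "")
  Fm <- class_frequency_matrix(ctx)
  expect_equal(dim(Fm), c(8000, 46))
  # one context: each column holds exactly one entry equal to 1
  expect_equal(colSums(Fm), rep(1, 46))
  expect_equal(colSums(Fm == 1), rep(1, 46))
  # the entry sits at the row of that position's triad
  for (j in c(1, 17, 46)) {
    expect_equal(Fm[triad_row_index(substr(ctx, j, j + 2)), j], 1)
  }
  # duplicated contexts leave frequencies unchanged
  expect_equal(class_frequency_matrix(c(ctx, ctx)), Fm)
  expect_error(class_frequency_matrix(character(0)), "empty")
})

test_that("frequency matrix matches direct substring counting", {
  set.seed(21)
  contexts <- replicate(5, paste(sample(AA20, 48, replace = TRUE),
                                 collapse = ""))
  Fm <- class_frequency_matrix(contexts)
  expect_equal(colSums(Fm), rep(1, 46), tolerance = 1e-12)
  # independent oracle: count each (triad, position) by hand
  for (j in seq(1, 46, by = 9)) {
    words <- substr(contexts, j, j + 2)
    for (w in unique(words)) {
      expect_equal(Fm[triad_row_index(w), j], mean(words == w))
    }
  }
})

test_that("identical class collections give a null propensity matrix", {
  set.seed(5)
  shared <- replicate(3, random_window())
  tab <- data.frame(protein_id = "p", center_pos = 25L,
                    residues = rep(shared, 11),
                    category = rep(1:11, each = 3), stringsAsFactors = FALSE)
  m <- fit_propensity(tab)
  expect_equal(m$F, m$FF, tolerance = 1e-12)
  expect_true(all(abs(m$F_mlpstaap) < 1e-12))
})

test_that("fitted frequencies match hand counting on a tiny two-motif set", {
  # categories differ only in their first triad; everything else constant
  base <- strrep("A", 45)
  ctxs <- c("CCC", "CCC", "DDD")  # class 1 gets CCC, CCC, DDD at position 1
  win1 <- vapply(paste0(ctxs, base), window_from_context, character(1))
  win_other <- window_from_context(paste0("EEE", base))
  tab <- data.frame(
    protein_id = "p", center_pos = 25L,
    residues = c(win1, rep(win_other, 10)),
    category = c(1L, 1L, 1L, 2:11), stringsAsFactors = FALSE)
  m <- fit_propensity(tab)
  rCCC <- triad_row_index("CCC")
  rEEE <- triad_row_index("EEE")
  # F = mean of per-class frequency columns: class 1 has 2/3 CCC, others 0
  expect_equal(m$F[rCCC, 1], (2 / 3) / 11)
  expect_equal(m$F[rEEE, 1], 10 / 11)
  # FF for class 1 is the frequency over the other 10 classes (all EEE);
  # each other class t sees class 1's windows among its complement of 12
  expect_equal(m$FF[rCCC, 1], mean(c(0, rep(2 / 12, 10))))
  expect_equal(m$F_mlpstaap[rCCC, 1], m$F[rCCC, 1] - m$FF[rCCC, 1])
})

test_that("fitting requires all 11 categories and ignores row order", {
  tab <- small_window_table(n_per = 3, seed = 8)
  expect_error(fit_propensity(tab[tab$category != 4, ]), "missing categor")
  m1 <- fit_propensity(tab)
  m2 <- fit_propensity(tab[rev(seq_len(nrow(tab))), ])
  expect_identical(m1$F_mlpstaap, m2$F_mlpstaap)
})

test_that("encoding looks up the propensity entry of each context triad", {
  tab <- small_window_table(n_per = 3, seed = 13)
  m <- fit_propensity(tab)
  # a context starting AGAT... must encode f[101, 1], f[2017, 2]
  set.seed(2)
  ctx <- paste0("AGAT", paste(sample(AA20, 44, replace = TRUE), collapse = ""))
  feat <- encode_windows(window_from_context(ctx), m)
  expect_equal(dim(feat), c(1, 46))
  expect_equal(feat[1, 1], m$F_mlpstaap[101, 1])
  expect_equal(feat[1, 2], m$F_mlpstaap[2017, 2])
  expect_true(all(feat >= -1 & feat <= 1))
  # zero matrix encodes to the zero vector
  m0 <- m
  m0$F_mlpstaap[] <- 0
  expect_equal(encode_windows(tab, m0), matrix(0, nrow(tab), 46))
  # X-containing triads encode as 0: fully padded left flank
  wpad <- paste0(strrep("X", 24), "K", strrep("A", 24))
  fpad <- encode_windows(wpad, m)
  expect_equal(fpad[1, 1:22], rep(0, 22))
})

test_that("a class-specific planted triad gets the top propensity of its column", {
  tab <- small_window_table(n_per = 12, seed = 17, prob = 1)
  m <- fit_propensity(tab)
  for (t in c(1, 4, 11)) {
    j <- 4 * (t - 1) + 3
    triad <- strrep(c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N")[t], 3)
    row <- triad_row_index(triad)
    expect_gt(m$F_mlpstaap[row, j], 0)
    expect_equal(which.max(m$F_mlpstaap[, j]), row)
  }
})
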