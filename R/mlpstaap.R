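# MLPSTAAP: multi-label position-specific triad amino-acid propensity.
#
# A 49-residue lysine-centered window, with its central K removed, yields a
# 48-residue context carrying 46 overlapping triads (3-residue words). For
# each of the 11 categories t we count the frequency F_t[i, j] of triad i at
# sliding position j; FF_t is the same frequency over the union of the other
# 10 categories. F and FF average the 11 per-class matrices, and the final
# propensity matrix is their difference. A window is encoded by looking up,
# for each of its 46 triads, the matrix entry at (triad row, position).

.N_TRIADS <- 8000L   # 20^3
.N_POS <- 46L        # triad positions in a 48-residue context

#' Row index of a triad in the propensity matrices
#'
#' Maps a 3-letter amino-acid word to its 1-based row using ranks over the
#' alphabet "A C D E F G H I K L M N P Q R S T V W Y" (A = 0 ... Y = 19):
#' `rank1 * 20^2 + rank2 * 20 + rank3 + 1`. The map is a bijection between
#' the 8000 triads and 1..8000.
#'
#' @param triad Character vector of 3-letter words.
#' @return Integer vector of row indices; NA for any word containing a letter
#'   outside the 20-letter alphabet (e.g. the padding letter 'X'), which
#'   callers encode as feature value 0.
#' @export
#' @examples
#' triad_row_index("AGA")  # 101
#' triad_row_index("GAT")  # 2017
triad_row_index <- function(triad) {
  stopifnot(all(nchar(triad) == 3L))
  chars <- matrix(unlist(strsplit(triad, ""), use.names = FALSE),
                  ncol = 3L, byrow = TRUE)
  r <- matrix(match(chars, .AA20) - 1L, ncol = 3L)
  as.integer(r[, 1L] * 400L + r[, 2L] * 20L + r[, 3L] + 1L)
}

#' 48-residue context of a window
#'
#' Concatenates the 24 left-flank and 24 right-flank residues, omitting the
#' central lysine.
#'
#' @param residues Character vector of 49-residue window strings.
#' @return Character vector of 48-residue context strings.
#' @export
context_of <- function(residues) {
  stopifnot(all(nchar(residues) == .WINDOW_LEN))
  paste0(substr(residues, 1L, .FLANK),
         substr(residues, .FLANK + 2L, .WINDOW_LEN))
}

# n x 46 matrix of triad row indices for a vector of 48-residue contexts
# (NA where the triad touches an 'X' or other out-of-alphabet letter).
.context_row_indices <- function(contexts) {
  stopifnot(all(nchar(contexts) == 2L * .FLANK))
  n <- length(contexts)
  chars <- matrix(unlist(strsplit(contexts, ""), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  r <- matrix(match(chars, .AA20) - 1L, nrow = n)
  idx <- r[, 1:.N_POS, drop = FALSE] * 400L +
    r[, 2:(.N_POS + 1L), drop = FALSE] * 20L +
    r[, 3:(.N_POS + 2L), drop = FALSE] + 1L
  matrix(as.integer(idx), nrow = n)
}

# 8000 x 46 matrix of raw triad counts for a set of contexts.
.triad_counts <- function(contexts) {
  idx <- .context_row_indices(contexts)
  counts <- matrix(0, nrow = .N_TRIADS, ncol = .N_POS)
  for (j in seq_len(.N_POS)) {
    v <- idx[, j]
    counts[, j] <- tabulate(v[!is.na(v)], nbins = .N_TRIADS)
  }
  counts
}

#' Positional triad frequency matrix of a set of contexts
#'
#' Entry (i, j) is the fraction of contexts whose triad at position j has row
#' index i. Triads containing 'X' contribute to no row; the denominator is
#' always the number of contexts, so columns over padded positions sum to
#' less than 1.
#'
#' @param contexts Character vector of 48-residue contexts (non-empty).
#' @return 8000 x 46 numeric matrix.
#' @export
class_frequency_matrix <- function(contexts) {
  if (length(contexts) == 0L) stop("empty context collection")
  .triad_counts(contexts) / length(contexts)
}

#' Fit the propensity model from categorized training windows
#'
#' For each category t, F_t is the positional triad frequency matrix of its
#' windows and FF_t the frequency matrix over the union of the other 10
#' categories' windows. F and FF are the unweighted means of the 11 F_t and
#' FF_t, and the propensity matrix is F - FF.
#'
#' @param windows Window table (see [build_windows()]) containing all 11
#'   categories.
#' @return Object of class `propensity_model`: list with `alphabet`, `F`,
#'   `FF`, `F_mlpstaap` (each 8000 x 46) and `class_sizes`.
#' @export
fit_propensity <- function(windows) {
  cats <- factor(windows$category, levels = 1:11)
  sizes <- as.integer(table(cats))
  missing <- which(sizes == 0L)
  if (length(missing) > 0L) {
    stop("cannot fit propensity model: missing categor(ies) ",
         paste(missing, collapse = ", "))
  }
  contexts <- context_of(windows$residues)
  by_cat <- split(contexts, cats)
  count_t <- lapply(by_cat, .triad_counts)
  total_counts <- Reduce(`+`, count_t)
  n_total <- length(contexts)

  Fsum <- matrix(0, .N_TRIADS, .N_POS)
  FFsum <- matrix(0, .N_TRIADS, .N_POS)
  for (t in 1:11) {
    Fsum <- Fsum + count_t[[t]] / sizes[t]
    FFsum <- FFsum + (total_counts - count_t[[t]]) / (n_total - sizes[t])
  }
  Fbar <- Fsum / 11
  FFbar <- FFsum / 11
  structure(
    list(alphabet = .AA20,
         F = Fbar,
         FF = FFbar,
         F_mlpstaap = Fbar - FFbar,
         class_sizes = stats::setNames(sizes, category_names())),
    class = "propensity_model"
  )
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Positional triad propensity model (", .N_TRIADS, " triads x ",
      .N_POS, " positions)\n", sep = "")
  cat("Fitted on", sum(x$class_sizes), "windows:\n")
  print(x$class_sizes)
  invisible(x)
}

#' Encode windows as 46-dimensional propensity feature vectors
#'
#' Feature j of a window is the propensity-matrix entry at the row of its
#' context triad at position j; triads containing 'X' encode as 0. All values
#' lie in [-1, 1].
#'
#' @param windows Window table, or a character vector of 49-residue window
#'   strings.
#' @param model Fitted `propensity_model`.
#' @return n x 46 numeric feature matrix.
#' @export
encode_windows <- function(windows, model) {
  stopifnot(inherits(model, "propensity_model"))
  residues <- if (is.character(windows)) windows else windows$residues
  idx <- .context_row_indices(context_of(residues))
  lin <- sweep(idx, 2L, (seq_len(.N_POS) - 1L) * .N_TRIADS, `+`)
  feat <- matrix(0, nrow = nrow(idx), ncol = .N_POS)
  ok <- !is.na(lin)
  feat[ok] <- model$F_mlpstaap[lin[ok]]
  feat
}
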