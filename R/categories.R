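# Modification-combination categories.
#
# Four lysine modification types are predicted: acetylation (A),
# crotonylation (C), methylation (M) and succinylation (S).  Of the 15
# non-empty combinations, 11 are admissible categories; the remaining 4
# ({C,S}, {M,S}, {A,M,S}, {C,M,S}) were too rare to form categories and are
# rejected at ingest.

#' Modification type tokens
#'
#' The four lysine modification types handled by the package, in canonical
#' order. Annotation files use these tokens; label vectors use the one-letter
#' abbreviations A, C, M, S.
#'
#' @format Character vector of length 4.
#' @export
MOD_TYPES <- c("acetyl", "crotonyl", "methyl", "succinyl")

#' One-letter abbreviations for the four modification types
#' @format Character vector of length 4 (A, C, M, S).
#' @export
MOD_LETTERS <- c("A", "C", "M", "S")

# 11 x 4 binary matrix: admissible label patterns, row t = category t.
.category_patterns <- matrix(
  c(1, 0, 0, 0,   # 1  A
    0, 1, 0, 0,   # 2  C
    0, 0, 1, 0,   # 3  M
    0, 0, 0, 1,   # 4  S
    1, 1, 0, 0,   # 5  A+C
    1, 0, 1, 0,   # 6  A+M
    1, 0, 0, 1,   # 7  A+S
    0, 1, 1, 0,   # 8  C+M
    1, 1, 1, 0,   # 9  A+C+M
    1, 1, 0, 1,   # 10 A+C+S
    1, 1, 1, 1),  # 11 A+C+M+S
  nrow = 11, ncol = 4, byrow = TRUE,
  dimnames = list(NULL, MOD_LETTERS)
)

#' Human-readable names of the 11 categories
#'
#' Concatenated one-letter codes ("A", "C", ..., "ACMS") in category order,
#' used as column headers in ratio-sweep tables and reports.
#'
#' @return Character vector of length 11.
#' @export
category_names <- function() {
  apply(.category_patterns, 1L, function(p) paste(MOD_LETTERS[p == 1], collapse = ""))
}

.pattern_key <- function(flags) paste(flags, collapse = "")
.category_lookup <- structure(
  seq_len(11L),
  names = apply(.category_patterns, 1L, .pattern_key)
)

#' Map a set of modification types to its category
#'
#' @param mods Character vector (a set) of modification tokens, a non-empty
#'   subset of `MOD_TYPES`.
#' @return Integer category id in 1..11.
#'
#' Combinations outside the 11 admissible categories (e.g. methyl+succinyl
#' alone) raise an error; callers assembling datasets catch it and drop the
#' record with a logged count.
#' @export
#' @examples
#' assign_category("acetyl")                 # 1
#' assign_category(c("acetyl", "crotonyl"))  # 5
assign_category <- function(mods) {
  mods <- unique(mods)
  bad <- setdiff(mods, MOD_TYPES)
  if (length(bad) > 0L) {
    stop("unknown modification token(s): ", paste(bad, collapse = ", "))
  }
  if (length(mods) == 0L) stop("empty modification set")
  flags <- as.integer(MOD_TYPES %in% mods)
  id <- .category_lookup[.pattern_key(flags)]
  if (is.na(id)) {
    stop("unsupported combination: {", paste(sort(mods), collapse = ", "),
         "} is not one of the 11 admissible categories")
  }
  unname(id)
}

#' One-hot label vector of a category
#'
#' @param category Integer vector of category ids in 1..11.
#' @return If one id, a named integer vector of 4 flags (A, C, M, S);
#'   if several, the corresponding matrix with one row per id.
#' @export
#' @examples
#' onehot_label(5)  # c(A = 1, C = 1, M = 0, S = 0)
onehot_label <- function(category) {
  stopifnot(is.numeric(category), all(category == as.integer(category)),
            all(category >= 1L), all(category <= 11L))
  out <- .category_patterns[category, , drop = FALSE]
  if (length(category) == 1L) out[1L, ] else out
}

#' Modification set of a category
#'
#' Inverse of [assign_category()]: the set of modification tokens of a
#' category id.
#'
#' @param category Integer in 1..11.
#' @return Character vector of tokens from `MOD_TYPES`.
#' @export
category_mods <- function(category) {
  stopifnot(length(category) == 1L, category >= 1, category <= 11)
  MOD_TYPES[.category_patterns[category, ] == 1]
}

#' Decode a binary flag vector into a label string
#'
#' @param flags Matrix (n x 4) or vector (length 4) of 0/1 flags in
#'   (A, C, M, S) order.
#' @return Character vector of concatenated letters; the all-zero pattern
#'   decodes to the empty string (no modification predicted).
#' @export
decode_flags <- function(flags) {
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1L)
  apply(flags, 1L, function(p) paste(MOD_LETTERS[p == 1], collapse = ""))
}

#' Category of a flag pattern, or NA if inadmissible
#'
#' @param flags Vector of 4 binary flags (A, C, M, S).
#' @return Integer category id, or NA for patterns outside the 11 categories
#'   (including the all-zero pattern).
#' @export
flags_to_category <- function(flags) {
  id <- .category_lookup[.pattern_key(as.integer(flags))]
  if (is.na(id)) NA_integer_ else unname(id)
}
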