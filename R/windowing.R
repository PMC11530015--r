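# Peptide windowing: FASTA + site annotations -> 49-residue lysine-centered
# windows with category labels.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.FLANK <- 24L
.WINDOW_LEN <- 2L * .FLANK + 1L  # 49

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector of upper-case sequences. Identifiers are truncated at the
#' first whitespace, matching common annotation-table conventions.
#'
#' @param path FASTA file path.
#' @return Named character vector of protein sequences.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Read a site-annotation table
#'
#' Tab-separated file with a header and columns `protein_id`, `position`
#' (1-based residue index of the annotated lysine) and `mods` (comma-separated
#' tokens among acetyl, crotonyl, methyl, succinyl).
#'
#' @param path TSV file path.
#' @return data.frame with columns protein_id (character), position (integer),
#'   mods (character).
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = TRUE)
  required <- c("protein_id", "position", "mods")
  missing <- setdiff(required, names(ann))
  if (length(missing) > 0L) {
    stop("annotation file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  ann$position <- as.integer(ann$position)
  ann[required]
}

# Normalize a residue character vector: upper-case; anything outside the
# 20-letter alphabet (B, J, O, U, Z, X, ...) becomes 'X'.
.normalize_residues <- function(chars, warn_context = NULL) {
  nonstd <- !(chars %in% .AA20) & chars != "X"
  if (any(nonstd)) {
    if (!is.null(warn_context)) {
      warning("normalized ", sum(nonstd), " non-standard residue(s) (",
              paste(unique(chars[nonstd]), collapse = ","), ") to 'X' in ",
              warn_context, call. = FALSE)
    }
    chars[nonstd] <- "X"
  }
  chars
}

#' Extract a 49-residue lysine-centered window
#'
#' Returns the residues at positions `position - 24 .. position + 24` of the
#' protein; positions falling outside the sequence are padded with 'X'.
#' Non-standard residues (B, J, O, U, Z) are normalized to 'X' with a warning.
#'
#' @param sequence Protein sequence (single string).
#' @param position 1-based index of the central lysine.
#' @param protein_id Optional identifier used in error messages.
#' @return A 49-character string whose 25th character is 'K'.
#' @export
extract_window <- function(sequence, position, protein_id = "<unnamed>") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    stop("position ", position, " outside protein ", protein_id,
         " (length ", n, ")")
  }
  chars <- strsplit(sequence, "")[[1]]
  if (chars[position] != "K") {
    stop("residue at position ", position, " of protein ", protein_id,
         " is '", chars[position], "', not 'K'; annotation rejected")
  }
  chars <- .normalize_residues(chars, warn_context = protein_id)
  idx <- (position - .FLANK):(position + .FLANK)
  win <- rep("X", .WINDOW_LEN)
  inside <- idx >= 1L & idx <= n
  win[inside] <- chars[idx[inside]]
  paste(win, collapse = "")
}

.check_window <- function(residues) {
  stopifnot(nchar(residues) == .WINDOW_LEN)
  stopifnot(substr(residues, .FLANK + 1L, .FLANK + 1L) == "K")
  # 'X' only as contiguous terminal padding
  chars <- strsplit(residues, "")[[1]]
  x <- which(chars == "X")
  if (length(x) > 0L) {
    lead <- x[x <= .FLANK]
    trail <- x[x > .FLANK + 1L]
    ok <- (length(lead) == 0L || identical(lead, seq_len(length(lead)))) &&
      (length(trail) == 0L ||
         identical(trail, seq.int(.WINDOW_LEN - length(trail) + 1L, .WINDOW_LEN)))
    if (!ok) stop("'X' occurs outside terminal padding in window: ", residues)
  }
  invisible(residues)
}

#' Build a window table from sequences and annotations
#'
#' Applies [extract_window()] and [assign_category()] to every annotation
#' record. Records whose modification combination is not one of the 11
#' admissible categories, or whose position does not hold a lysine, are
#' dropped with a summary warning.
#'
#' @param sequences Named character vector of protein sequences (see
#'   [read_fasta()]).
#' @param annotations data.frame from [read_annotations()].
#' @return data.frame with columns protein_id, center_pos, residues, category.
#' @export
build_windows <- function(sequences, annotations) {
  n <- nrow(annotations)
  out <- vector("list", n)
  n_unsupported <- 0L
  n_rejected <- 0L
  for (i in seq_len(n)) {
    pid <- annotations$protein_id[i]
    pos <- annotations$position[i]
    mods <- strsplit(annotations$mods[i], ",")[[1]]
    mods <- trimws(mods[nzchar(trimws(mods))])
    if (!pid %in% names(sequences)) {
      n_rejected <- n_rejected + 1L
      next
    }
    cat_id <- tryCatch(assign_category(mods), error = function(e) NA_integer_)
    if (is.na(cat_id)) {
      n_unsupported <- n_unsupported + 1L
      next
    }
    res <- tryCatch(extract_window(sequences[[pid]], pos, pid),
                    error = function(e) NA_character_)
    if (is.na(res)) {
      n_rejected <- n_rejected + 1L
      next
    }
    out[[i]] <- data.frame(protein_id = pid, center_pos = pos,
                           residues = res, category = cat_id,
                           stringsAsFactors = FALSE)
  }
  if (n_unsupported > 0L) {
    warning(n_unsupported, " record(s) with unsupported modification ",
            "combinations excluded", call. = FALSE)
  }
  if (n_rejected > 0L) {
    warning(n_rejected, " record(s) rejected (unknown protein, bad position ",
            "or non-lysine residue)", call. = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(protein_id = character(), center_pos = integer(),
                      residues = character(), category = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Remove duplicate peptide windows
#'
#' Exactly one window is retained per distinct residue string. When duplicates
#' carry different categories, their modification sets are unioned and the
#' category reassigned; if the union is not an admissible category the window
#' is dropped, both events with a logged warning.
#'
#' @param windows Window table from [build_windows()].
#' @return Deduplicated window table (first occurrence retained, category
#'   possibly updated).
#' @export
deduplicate <- function(windows) {
  if (nrow(windows) == 0L) return(windows)
  groups <- split(seq_len(nrow(windows)), windows$residues)
  keep <- integer(0)
  new_cat <- integer(0)
  n_merged <- 0L
  n_dropped <- 0L
  for (idx in groups) {
    first <- idx[1L]
    cats <- unique(windows$category[idx])
    if (length(cats) == 1L) {
      keep <- c(keep, first)
      new_cat <- c(new_cat, cats)
    } else {
      mods <- unique(unlist(lapply(cats, category_mods)))
      merged <- tryCatch(assign_category(mods), error = function(e) NA_integer_)
      if (is.na(merged)) {
        n_dropped <- n_dropped + 1L
      } else {
        n_merged <- n_merged + 1L
        keep <- c(keep, first)
        new_cat <- c(new_cat, merged)
      }
    }
  }
  if (n_merged > 0L) {
    warning(n_merged, " duplicate window(s) had conflicting categories; ",
            "modification sets unioned and category reassigned", call. = FALSE)
  }
  if (n_dropped > 0L) {
    warning(n_dropped, " duplicate window(s) unioned to an inadmissible ",
            "combination and were dropped", call. = FALSE)
  }
  ord <- sort.int(keep, index.return = TRUE)
  out <- windows[ord$x, , drop = FALSE]
  out$category <- new_cat[ord$ix]
  rownames(out) <- NULL
  out
}

#' Filter out sparsely populated categories
#'
#' @param windows Window table.
#' @param min_per_category Minimum windows a category must have to be kept
#'   (default 60).
#' @return Filtered window table.
#' @export
filter_categories <- function(windows, min_per_category = 60L) {
  counts <- table(factor(windows$category, levels = 1:11))
  keep_cats <- as.integer(names(counts)[counts >= min_per_category])
  dropped <- setdiff(unique(windows$category), keep_cats)
  if (length(dropped) > 0L) {
    warning("dropped ", sum(!windows$category %in% keep_cats), " window(s) in ",
            length(dropped), " categor(ies) below the ", min_per_category,
            "-window floor", call. = FALSE)
  }
  out <- windows[windows$category %in% keep_cats, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Category-stratified train/test split
#'
#' Within each category, `round(train_fraction * n)` windows are drawn at
#' random for training and the remainder held out. Categories with fewer than
#' 2 members go entirely to training with a warning.
#'
#' @param windows Window table.
#' @param train_fraction Fraction in (0, 1), default 0.7.
#' @param seed Integer RNG seed; the split is reproducible given the seed.
#' @return List with elements `train` and `test` (window tables).
#' @export
split_dataset <- function(windows, train_fraction = 0.7, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  rng <- .local_rng(seed)
  on.exit(rng())
  train_idx <- integer(0)
  for (cat_id in sort(unique(windows$category))) {
    idx <- which(windows$category == cat_id)
    n_c <- length(idx)
    if (n_c < 2L) {
      warning("category ", cat_id, " has ", n_c,
              " window(s); all assigned to training", call. = FALSE)
      train_idx <- c(train_idx, idx)
      next
    }
    n_train <- .round_half_up(train_fraction * n_c)
    n_train <- min(max(n_train, 1L), n_c - 1L)
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  train_idx <- sort(train_idx)
  list(train = windows[train_idx, , drop = FALSE],
       test = windows[setdiff(seq_len(nrow(windows)), train_idx), , drop = FALSE])
}

#' Write / read a window table as TSV
#'
#' Serialization carries protein_id, center_pos, residues, category and the
#' decoded label pattern.
#'
#' @param windows Window table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(windows, path) {
  lab <- decode_flags(onehot_label(windows$category))
  out <- cbind(windows, label = lab)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @export
read_windows <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  df$center_pos <- as.integer(df$center_pos)
  df$category <- as.integer(df$category)
  df[c("protein_id", "center_pos", "residues", "category")]
}
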