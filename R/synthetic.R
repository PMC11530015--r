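# Seeded synthetic benchmark data.
#
# Windows are 48 i.i.d. background residues with the central 'K' inserted;
# each category plants position-specific triad motifs with a given
# probability, which is exactly the statistical structure the propensity
# encoder is designed to detect: class-specific positional triad enrichment.
# The default spec reproduces, at reduced scale, the severe majority-class
# imbalance of real lysine-modification training sets
# (9279:710:600:454:561:252:360:88:153:454:73).

.BASE_TRAIN_COUNTS <- c(9279L, 710L, 600L, 454L, 561L, 252L, 360L, 88L,
                        153L, 454L, 73L)

#' Build a synthetic-data specification
#'
#' @param category_counts Integer vector of 11 window counts (zeros allowed
#'   only where the consuming test tolerates missing categories).
#' @param motifs List of 11 elements, one per category; each element a list
#'   of motifs, each motif a list with `position` (context position in
#'   1..46), `triad` (3-letter word over the 20-letter alphabet) and `prob`
#'   (planting probability in `[0, 1]`). Motifs of one category may not
#'   overlap in position.
#' @param background Residue distribution over the 20 letters (default
#'   uniform).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(category_counts, motifs, background = rep(1 / 20, 20),
                           seed = 1L) {
  stopifnot(length(category_counts) == 11L, all(category_counts >= 0),
            length(motifs) == 11L, length(background) == 20L,
            abs(sum(background) - 1) < 1e-8, all(background >= 0))
  for (t in 1:11) {
    for (m in motifs[[t]]) {
      stopifnot(m$position >= 1L, m$position <= 46L,
                nchar(m$triad) == 3L, !is.na(triad_row_index(m$triad)),
                m$prob >= 0, m$prob <= 1)
    }
    pos <- vapply(motifs[[t]], `[[`, numeric(1L), "position")
    if (length(pos) > 1L) {
      span <- unlist(lapply(pos, function(p) p:(p + 2L)))
      if (anyDuplicated(span)) {
        stop("overlapping motifs within category ", t)
      }
    }
  }
  structure(list(category_counts = as.integer(category_counts),
                 motifs = motifs, background = background,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default imbalanced synthetic specification
#'
#' Category counts proportional to the reference training ratio
#' 9279:710:600:454:561:252:360:88:153:454:73, scaled by `scale` with a floor
#' of 8 windows per category (so 5-fold stratification stays possible), and
#' one distinct strong motif per category: category t plants its own triad
#' (a tripled letter, K excluded) at context position `4 (t - 1) + 3` with
#' probability 0.9.
#'
#' @param seed Integer seed.
#' @param scale Scaling factor for the category counts (default 0.1).
#' @return `synthetic_spec`.
#' @export
default_imbalanced_spec <- function(seed = 1L, scale = 0.1) {
  counts <- pmax(8L, .round_half_up(.BASE_TRAIN_COUNTS * scale))
  letters11 <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N")
  motifs <- lapply(1:11, function(t) {
    list(list(position = 4L * (t - 1L) + 3L,
              triad = strrep(letters11[t], 3L),
              prob = 0.9))
  })
  synthetic_spec(counts, motifs, seed = seed)
}

#' Generate synthetic peptide windows
#'
#' @param spec [synthetic_spec()].
#' @return Window table (protein_id, center_pos, residues, category); one
#'   synthetic protein per window, center_pos 25.
#' @export
generate_windows <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rng <- .local_rng(spec$seed)
  on.exit(rng())
  pieces <- vector("list", 11L)
  for (t in 1:11) {
    n <- spec$category_counts[t]
    if (n == 0L) next
    ctx <- matrix(sample(.AA20, n * 48L, replace = TRUE,
                         prob = spec$background),
                  nrow = n, ncol = 48L)
    for (m in spec$motifs[[t]]) {
      plant <- stats::runif(n) < m$prob
      if (any(plant)) {
        letters3 <- strsplit(m$triad, "")[[1]]
        # motif occupies context positions j, j+1, j+2
        for (o in 0:2) ctx[plant, m$position + o] <- letters3[o + 1L]
      }
    }
    ctx_str <- apply(ctx, 1L, paste, collapse = "")
    residues <- paste0(substr(ctx_str, 1L, 24L), "K",
                       substr(ctx_str, 25L, 48L))
    pieces[[t]] <- data.frame(
      protein_id = sprintf("SYN_C%02d_%05d", t, seq_len(n)),
      center_pos = 25L,
      residues = residues,
      category = t,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1L))])
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset as FASTA + annotation TSV
#'
#' Each window becomes its own synthetic protein (the 49-mer itself), with an
#' annotation record at position 25, so the synthetic data flows through the
#' same FASTA/TSV entry point as real data.
#'
#' @param windows Window table from [generate_windows()].
#' @param fasta_path,annotations_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_synthetic_dataset <- function(windows, fasta_path, annotations_path) {
  seqs <- Biostrings::AAStringSet(stats::setNames(windows$residues,
                                                  windows$protein_id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  mods <- vapply(windows$category,
                 function(t) paste(category_mods(t), collapse = ","),
                 character(1L))
  ann <- data.frame(protein_id = windows$protein_id,
                    position = windows$center_pos,
                    mods = mods, stringsAsFactors = FALSE)
  utils::write.table(ann, annotations_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, annotations = annotations_path))
}
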