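# -- motif primitives ---------------------------------------------------------
# All IRR detection reduces to: does this read tile (almost) perfectly with
# some rotation of a 2-6 bp motif, on either strand?  Motifs are keyed by a
# canonical representative so that reads from either strand and any repeat
# phase collapse into one motif class.

.valid_motif <- function(motif) {
  is.character(motif) && length(motif) == 1L && !is.na(motif) &&
    nchar(motif) >= 2L && nchar(motif) <= 6L &&
    grepl("^[ACGT]+$", motif)
}

.check_motif <- function(motif) {
  if (!.valid_motif(motif)) {
    stop("invalid motif '", motif,
         "': must be a 2-6 bp string over {A,C,G,T}", call. = FALSE)
  }
  invisible(motif)
}

#' Reverse complement of a DNA string
#'
#' Plain-string reverse complement over the ACGTN alphabet. Used for motif
#' canonicalization and for trying spanning-read anchors in both read
#' orientations.
#'
#' @param x Character vector of DNA strings (A, C, G, T, N).
#' @return Character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' All rotations of a motif
#'
#' @param motif A 2-6 bp motif string.
#' @return Character vector of the \code{nchar(motif)} rotations, starting at
#'   offset 0.
#' @export
rotations <- function(motif) {
  .check_motif(motif)
  k <- nchar(motif)
  doubled <- paste0(motif, motif)
  vapply(seq_len(k), function(i) substr(doubled, i, i + k - 1L), character(1))
}

#' Canonical representative of a motif class
#'
#' Two repeat motifs describe the same tandem repeat if one is a rotation of
#' the other or of its reverse complement (the same tract read in a different
#' phase or from the other strand).  The canonical representative is the
#' lexicographically smallest string among all rotations of the motif and all
#' rotations of its reverse complement; e.g. CAG, AGC, GCA, CTG, TGC and GCT
#' all canonicalize to AGC.
#'
#' @param motif A 2-6 bp motif string over \{A,C,G,T\}.
#' @return The canonical motif string (same length).
#' @examples
#' canonicalize_motif("CAG")   # "AGC"
#' canonicalize_motif("AAAG")  # "AAAG"
#' @export
canonicalize_motif <- function(motif) {
  .check_motif(motif)
  min(c(rotations(motif), rotations(revcomp(motif))))
}

#' Repeat-purity score of a read against a motif
#'
#' The fraction of read positions consistent with a perfect tiling of some
#' rotation of the motif (both strands considered).  This quantifies "entirely
#' or almost entirely" repeat sequence: a pure in-repeat read scores 1.
#' Purity counts substitutions only; a read whose best explanation requires an
#' internal indel simply scores low.  N bases count as mismatches.
#'
#' @param read_seq Non-empty read sequence string.
#' @param motif A 2-6 bp motif; rotations of the canonical form and of its
#'   reverse complement are all tried.
#' @return A list with \code{value} (best fraction matching, in [0,1]),
#'   \code{best_rotation} (the arg-max rotation; ties broken by rotation
#'   order of the canonical form, forward strand first) and
#'   \code{mismatch_positions} (0-based read offsets mismatching the best
#'   rotation).
#' @export
purity <- function(read_seq, motif) {
  if (!is.character(read_seq) || length(read_seq) != 1L || is.na(read_seq) ||
      nchar(read_seq) == 0L) {
    stop("read_seq must be a non-empty string", call. = FALSE)
  }
  canon <- canonicalize_motif(motif)
  rots <- unique(c(rotations(canon), rotations(revcomp(canon))))
  n <- nchar(read_seq)
  read_int <- utf8ToInt(read_seq)
  best_val <- -1
  best_rot <- NULL
  best_mm <- NULL
  for (r in rots) {
    k <- nchar(r)
    tiled <- utf8ToInt(strrep(r, ceiling(n / k)))[seq_len(n)]
    mm <- which(read_int != tiled) - 1L
    val <- 1 - length(mm) / n
    if (val > best_val) {
      best_val <- val
      best_rot <- r
      best_mm <- mm
    }
  }
  list(value = best_val, best_rotation = best_rot,
       mismatch_positions = best_mm)
}

#' Is a read an in-repeat read (IRR)?
#'
#' @param read_seq Read sequence string.
#' @param motif A 2-6 bp motif.
#' @param tau Purity threshold in (0, 1]; default 0.95. The threshold is a
#'   configurable knob: pure reads score 1 and "almost entirely" repeat reads
#'   score slightly below.
#' @return TRUE iff \code{purity(read_seq, motif)$value >= tau}.
#' @export
is_irr <- function(read_seq, motif, tau = 0.95) {
  stopifnot(tau > 0, tau <= 1)
  purity(read_seq, motif)$value >= tau
}

# Vectorized purity values for many reads against one canonical motif class.
# Returns the best purity per read; used by detect_irrs on read batches.
purity_batch <- function(read_seqs, motif) {
  canon <- canonicalize_motif(motif)
  rots <- unique(c(rotations(canon), rotations(revcomp(canon))))
  n_read <- length(read_seqs)
  if (n_read == 0L) return(numeric(0))
  lens <- nchar(read_seqs)
  best <- rep(-1, n_read)
  maxlen <- max(lens)
  ints <- lapply(read_seqs, utf8ToInt)
  for (r in rots) {
    k <- nchar(r)
    tiled_full <- utf8ToInt(strrep(r, ceiling(maxlen / k) + 1L))
    vals <- vapply(seq_len(n_read), function(i) {
      ri <- ints[[i]]
      1 - sum(ri != tiled_full[seq_along(ri)]) / lens[i]
    }, numeric(1))
    best <- pmax(best, vals)
  }
  best
}
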