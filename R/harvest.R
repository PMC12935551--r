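# -- repeat harvest -----------------------------------------------------------
# Scans read records for in-repeat reads (IRRs), assigns them to catalog loci
# through their mate's alignment, pairs up fragments whose two mates are both
# IRRs (evidence of very long alleles), measures allele lengths from reads
# that span the whole tract, and derives per-sample germline genotypes.

#' Excluded-result marker
#'
#' Operations that can decline to produce a result (insufficient coverage,
#' ineligible allele configuration, ...) return an excluded marker instead
#' of a value; \code{is_excluded} tests for it and \code{x$reason} carries
#' the machine-readable reason string used in pipeline accounting.
#'
#' @param reason Reason string.
#' @return An object of class \code{strh_excluded}.
#' @export
excluded <- function(reason) {
  structure(list(reason = reason), class = "strh_excluded")
}

#' @rdname excluded
#' @param x Object to test.
#' @export
is_excluded <- function(x) inherits(x, "strh_excluded")

#' Harvest parameter set
#'
#' @param tau IRR purity threshold (default 0.95).
#' @param window_bp Mate-to-locus assignment window in bp (default 500).
#' @param min_anchor_bp Exact flank anchor length required on both sides of a
#'   spanning call (default 10).
#' @param min_support Minimum reads supporting a germline allele (default 2).
#' @param minor_frac Minimum fraction of the top allele's support required to
#'   call a second allele (default 0.2).
#' @param max_interrupted_units Spanning calls with more interrupted units
#'   than this are rejected (default 3).
#' @return A named list of parameters.
#' @export
harvest_params <- function(tau = 0.95, window_bp = 500L, min_anchor_bp = 10L,
                           min_support = 2L, minor_frac = 0.2,
                           max_interrupted_units = 3L) {
  stopifnot(tau > 0, tau <= 1, window_bp > 0, min_anchor_bp >= 4,
            min_support >= 1, minor_frac >= 0, minor_frac <= 1)
  list(tau = tau, window_bp = as.integer(window_bp),
       min_anchor_bp = as.integer(min_anchor_bp),
       min_support = as.integer(min_support), minor_frac = minor_frac,
       max_interrupted_units = as.integer(max_interrupted_units))
}

#' Detect in-repeat reads
#'
#' Flags reads consisting entirely or almost entirely of tandem copies of a
#' motif (any rotation, either strand).  A read qualifying for several motif
#' classes (possible for degenerate motifs) is reported once, for the class
#' with highest purity; ties go to the lexicographically smallest canonical
#' motif.
#'
#' @param reads Read-record data.frame (see \code{\link{read_alignments}}).
#' @param motifs Character vector of motifs (canonicalized internally).
#' @param tau Purity threshold.
#' @return data.frame of IRR calls: \code{read_id}, \code{fragment_id},
#'   \code{mate_index}, \code{sample_id}, \code{motif}, \code{purity_value}.
#' @export
detect_irrs <- function(reads, motifs, tau = 0.95) {
  stopifnot(tau > 0, tau <= 1)
  canon <- sort(unique(vapply(motifs, canonicalize_motif, character(1))))
  if (nrow(reads) == 0L) {
    return(data.frame(read_id = character(0), fragment_id = character(0),
                      mate_index = integer(0), sample_id = character(0),
                      motif = character(0), purity_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  pur <- sapply(canon, function(m) purity_batch(reads$seq, m))
  pur <- matrix(pur, nrow = nrow(reads),
                dimnames = list(NULL, canon))
  best_idx <- apply(pur, 1L, which.max)
  best_val <- pur[cbind(seq_len(nrow(pur)), best_idx)]
  keep <- best_val >= tau
  data.frame(
    read_id = reads$read_id[keep],
    fragment_id = reads$fragment_id[keep],
    mate_index = reads$mate_index[keep],
    sample_id = reads$sample_id[keep],
    motif = canon[best_idx[keep]],
    purity_value = best_val[keep],
    stringsAsFactors = FALSE
  )
}

# Distance in bp between two half-open intervals; 0 when they overlap.
.interval_distance <- function(s1, e1, s2, e2) {
  ifelse(e1 <= s2, s2 - e1, ifelse(e2 <= s1, s1 - e2, 0L))
}

#' Assign IRR calls to catalog loci via mate position
#'
#' An IRR itself usually has no reliable alignment (it is pure repeat), but
#' its mate often anchors in unique flanking sequence.  An IRR is assigned to
#' the unique catalog locus of the same canonical motif whose tract lies
#' within \code{window_bp} of the mate's aligned interval; zero or several
#' candidates leave it unassigned with a recorded reason.
#'
#' @param irrs IRR call data.frame from \code{\link{detect_irrs}}.
#' @param reads Read-record data.frame (to look up each IRR's own record,
#'   which carries the mate coordinates).
#' @param catalog Catalog data.frame from \code{\link{read_catalog}}.
#' @param window_bp Assignment window (default 500).
#' @return The IRR table with \code{assigned_locus},
#'   \code{assignment_distance} and \code{assign_reason} columns
#'   (\code{assigned}, \code{mate-unmapped}, \code{no-locus-in-window},
#'   \code{ambiguous}).
#' @export
assign_locus <- function(irrs, reads, catalog, window_bp = 500L) {
  stopifnot(window_bp > 0)
  irrs$assigned_locus <- rep(NA_character_, nrow(irrs))
  irrs$assignment_distance <- rep(NA_integer_, nrow(irrs))
  irrs$assign_reason <- rep(NA_character_, nrow(irrs))
  if (nrow(irrs) == 0L) return(irrs)
  idx <- match(irrs$read_id, reads$read_id)
  read_len <- nchar(reads$seq[idx])
  mate_chrom <- reads$mate_chrom[idx]
  mate_pos <- reads$mate_pos[idx]
  for (i in seq_len(nrow(irrs))) {
    if (is.na(mate_chrom[i]) || is.na(mate_pos[i])) {
      irrs$assign_reason[i] <- "mate-unmapped"
      next
    }
    cand <- catalog[catalog$motif_canonical == irrs$motif[i] &
                      catalog$chrom == mate_chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L) {
      irrs$assign_reason[i] <- "no-locus-in-window"
      next
    }
    d <- .interval_distance(mate_pos[i], mate_pos[i] + read_len[i],
                            cand$start, cand$end)
    hit <- which(d <= window_bp)
    if (length(hit) == 1L) {
      irrs$assigned_locus[i] <- cand$locus_id[hit]
      irrs$assignment_distance[i] <- as.integer(d[hit])
      irrs$assign_reason[i] <- "assigned"
    } else if (length(hit) == 0L) {
      irrs$assign_reason[i] <- "no-locus-in-window"
    } else {
      irrs$assign_reason[i] <- "ambiguous"
    }
  }
  irrs
}

#' Find IRR pairs
#'
#' A fragment whose two mates are both IRRs for the same motif must fit
#' entirely inside a repeat tract, implying an allele roughly as long as the
#' fragment (about 100+ units for a trinucleotide repeat at typical insert
#' sizes).  Since neither mate anchors in flank, the pair's locus is taken
#' from single-IRR evidence: the unique locus at which the same sample has at
#' least one assigned single IRR of that motif, else \code{ambiguous}.
#'
#' @param irrs Assigned IRR table from \code{\link{assign_locus}}.
#' @return data.frame: \code{fragment_id}, \code{sample_id}, \code{motif},
#'   \code{assigned_locus} (locus id or \code{"ambiguous"}).
#' @export
find_irr_pairs <- function(irrs) {
  empty <- data.frame(fragment_id = character(0), sample_id = character(0),
                      motif = character(0), assigned_locus = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(irrs) == 0L) return(empty)
  key <- paste(irrs$sample_id, irrs$fragment_id, irrs$motif, sep = "\r")
  tab <- table(key)
  pair_keys <- names(tab)[tab >= 2L]
  if (length(pair_keys) == 0L) return(empty)
  parts <- strsplit(pair_keys, "\r", fixed = TRUE)
  out <- data.frame(
    fragment_id = vapply(parts, `[[`, character(1), 2L),
    sample_id = vapply(parts, `[[`, character(1), 1L),
    motif = vapply(parts, `[[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  out$assigned_locus <- vapply(seq_len(nrow(out)), function(i) {
    anchored <- irrs$assigned_locus[
      irrs$sample_id == out$sample_id[i] & irrs$motif == out$motif[i] &
        !is.na(irrs$assigned_locus)]
    u <- unique(anchored)
    if (length(u) == 1L) u else "ambiguous"
  }, character(1))
  out[order(out$sample_id, out$fragment_id, out$motif), , drop = FALSE]
}

#' Measure a repeat allele from a read spanning the whole tract
#'
#' Requires an exact match of at least \code{min_anchor_bp} to the end of the
#' left flank immediately before the repeat and to the start of the right
#' flank immediately after it, tried in both read orientations.  The repeat
#' segment between the anchors is counted in motif units against its best
#' rotation; units differing by substitutions are recorded as interruptions
#' (an indel inside the tract simply changes the measured length, which is a
#' distinct length observation, not an interruption).
#'
#' @param read_seq Read sequence.
#' @param read_qual Phred+33 quality string (carried through for downstream
#'   stutter assessment; may be NULL).
#' @param entry One catalog row (list or single-row data.frame).
#' @param min_anchor_bp Anchor length (default 10).
#' @param max_interrupted_units Reject calls with more interrupted units
#'   (default 3).
#' @return A list (class \code{spanning_call}) with \code{unit_count},
#'   \code{bp_length}, \code{interruptions} (data.frame unit_index/observed),
#'   \code{left_anchor_len}, \code{right_anchor_len},
#'   \code{repeat_end_offset} (0-based read offset of the first base after
#'   the tract, in the matched orientation), \code{orientation}
#'   (\code{"+"}/\code{"-"}), \code{repeat_unit} (the tract's repeat unit in
#'   the matched orientation, phase-aligned to the tract start) — or NULL
#'   when the read does not span the tract.
#' @export
call_spanning <- function(read_seq, read_qual, entry, min_anchor_bp = 10L,
                          max_interrupted_units = 3L) {
  entry <- as.list(entry)
  if (nchar(entry$left_flank) < min_anchor_bp ||
      nchar(entry$right_flank) < min_anchor_bp) {
    stop("catalog flanks shorter than min_anchor_bp", call. = FALSE)
  }
  la <- substr(entry$left_flank,
               nchar(entry$left_flank) - min_anchor_bp + 1L,
               nchar(entry$left_flank))
  ra <- substr(entry$right_flank, 1L, min_anchor_bp)
  k <- nchar(entry$motif)
  for (orient in c("+", "-")) {
    s <- if (orient == "+") read_seq else revcomp(read_seq)
    hit <- .span_anchor(s, la, ra, min_anchor_bp)
    if (is.null(hit)) next
    seg <- substr(s, hit$rep_start, hit$rep_end)
    seg_len <- nchar(seg)
    unit_count <- seg_len %/% k
    res <- .judge_units(seg, entry$motif, k, unit_count)
    if (nrow(res$interruptions) > max_interrupted_units) next
    return(structure(list(
      unit_count = unit_count,
      bp_length = seg_len,
      interruptions = res$interruptions,
      left_anchor_len = min_anchor_bp,
      right_anchor_len = min_anchor_bp,
      repeat_end_offset = hit$rep_end,  # 0-based offset of first base after
      orientation = orient,
      repeat_unit = res$unit
    ), class = "spanning_call"))
  }
  NULL
}

# Locate the left anchor occurrence closest to the tract (the last one that
# still has a right-anchor occurrence after it), then the first right-anchor
# occurrence at or after the repeat start. 1-based rep_start / rep_end is
# half-open in 0-based terms: rep_end equals the 0-based offset of the first
# base after the tract.
.span_anchor <- function(s, la, ra, min_anchor_bp) {
  lpos_all <- gregexpr(la, s, fixed = TRUE)[[1]]
  if (lpos_all[1] < 0L) return(NULL)
  rpos_all <- gregexpr(ra, s, fixed = TRUE)[[1]]
  if (rpos_all[1] < 0L) return(NULL)
  for (lpos in rev(as.integer(lpos_all))) {
    rep_start <- lpos + min_anchor_bp            # 1-based
    rhits <- rpos_all[rpos_all >= rep_start]
    if (length(rhits)) {
      return(list(rep_start = rep_start,
                  rep_end = as.integer(rhits[1]) - 1L))
    }
  }
  NULL
}

# Count complete units against the best rotation and record interruptions.
.judge_units <- function(seg, motif, k, unit_count) {
  empty <- data.frame(unit_index = integer(0), observed = character(0),
                      stringsAsFactors = FALSE)
  if (unit_count == 0L) return(list(unit = motif, interruptions = empty))
  p <- purity(seg, motif)
  unit <- p$best_rotation
  tiled <- strrep(unit, unit_count)
  starts <- (seq_len(unit_count) - 1L) * k + 1L
  obs <- substring(seg, starts, starts + k - 1L)
  exp_u <- substring(tiled, starts, starts + k - 1L)
  bad <- which(obs != exp_u)
  list(unit = unit,
       interruptions = data.frame(unit_index = bad, observed = obs[bad],
                                  stringsAsFactors = FALSE))
}

# Batch spanning caller over a read table for one catalog entry; returns a
# flat data.frame (one row per spanning read) with interruptions serialized
# as "idx:OBS" semicolon-joined.
.call_spanning_batch <- function(reads, entry, params) {
  calls <- lapply(seq_len(nrow(reads)), function(i) {
    call_spanning(reads$seq[i], reads$qual[i], entry,
                  params$min_anchor_bp, params$max_interrupted_units)
  })
  keep <- !vapply(calls, is.null, logical(1))
  if (!any(keep)) {
    return(data.frame(locus_id = character(0), sample_id = character(0),
                      read_id = character(0), unit_count = integer(0),
                      bp_length = integer(0), interruption_sig = character(0),
                      repeat_end_offset = integer(0),
                      orientation = character(0), repeat_unit = character(0),
                      stringsAsFactors = FALSE))
  }
  calls <- calls[keep]
  data.frame(
    locus_id = entry$locus_id,
    sample_id = reads$sample_id[keep],
    read_id = reads$read_id[keep],
    unit_count = vapply(calls, `[[`, integer(1), "unit_count"),
    bp_length = vapply(calls, `[[`, integer(1), "bp_length"),
    interruption_sig = vapply(calls, function(cl) {
      ir <- cl$interruptions
      if (nrow(ir) == 0L) "" else
        paste(paste0(ir$unit_index, ":", ir$observed), collapse = ";")
    }, character(1)),
    repeat_end_offset = vapply(calls, `[[`, integer(1), "repeat_end_offset"),
    orientation = vapply(calls, `[[`, character(1), "orientation"),
    repeat_unit = vapply(calls, `[[`, character(1), "repeat_unit"),
    stringsAsFactors = FALSE
  )
}

#' Call a germline repeat genotype from spanning reads
#'
#' Takes the one or two best-supported unit lengths as the germline alleles.
#' The second allele is retained only when its support reaches
#' \code{max(min_support, minor_frac * top_count)}; all remaining lengths are
#' candidate somatic observations, not alleles.
#'
#' @param unit_counts Integer vector of per-read unit counts for one sample
#'   at one locus.
#' @param min_support Minimum supporting reads per allele (default 2).
#' @param minor_frac Minimum fraction of top-allele support for the second
#'   allele (default 0.2).
#' @return List with \code{alleles} (sorted ascending, length 2 — a
#'   homozygote repeats the allele) and \code{support} (read counts per
#'   allele), or an \code{\link{excluded}} marker when coverage is
#'   insufficient.
#' @export
genotype_sample <- function(unit_counts, min_support = 2L, minor_frac = 0.2) {
  if (length(unit_counts) < min_support) {
    return(excluded("insufficient-coverage"))
  }
  tab <- sort(table(unit_counts), decreasing = TRUE)
  lens <- as.integer(names(tab))
  if (tab[1] < min_support) {
    return(excluded("insufficient-support"))
  }
  alleles <- lens[1]
  support <- as.integer(tab[1])
  if (length(tab) >= 2L &&
      tab[2] >= max(min_support, minor_frac * tab[1])) {
    alleles <- c(alleles, lens[2])
    support <- c(support, as.integer(tab[2]))
  } else {
    alleles <- c(alleles, alleles)
    support <- c(support, support)
  }
  ord <- order(alleles)
  list(alleles = alleles[ord], support = support[ord])
}

#' Run the full harvest over a read table
#'
#' For each read near a catalog tract a spanning call is attempted first
#' (spanning and IRR calls are mutually exclusive per read; spanning takes
#' precedence).  Remaining reads are screened as IRRs for the catalog's motif
#' classes, assigned via mates, and paired.  Germline genotypes are derived
#' per sample and locus from the spanning calls.
#'
#' @param reads Read-record data.frame.
#' @param catalog Catalog data.frame.
#' @param params Parameter list from \code{\link{harvest_params}}.
#' @return List of data.frames: \code{spanning}, \code{irr},
#'   \code{irr_pairs}, \code{genotypes}, plus \code{skip_counts} (named
#'   integer accounting of unassigned/skip reasons).
#' @export
harvest_reads <- function(reads, catalog, params = harvest_params()) {
  span_list <- lapply(seq_len(nrow(catalog)), function(j) {
    entry <- as.list(catalog[j, ])
    # candidate reads: mapped within 2 read-lengths of the tract
    rl <- if (nrow(reads)) max(nchar(reads$seq)) else 151L
    cand <- reads[!is.na(reads$chrom) & reads$chrom == entry$chrom &
                    !is.na(reads$pos) &
                    reads$pos >= entry$start - 2L * rl &
                    reads$pos <= entry$end + 2L * rl, , drop = FALSE]
    .call_spanning_batch(cand, entry, params)
  })
  spanning <- do.call(rbind, span_list)
  if (is.null(spanning) || nrow(spanning) == 0L) {
    spanning <- .call_spanning_batch(reads[0, , drop = FALSE],
                                     as.list(catalog[1, ]), params)
  }
  spanning <- spanning[order(spanning$sample_id, spanning$locus_id,
                             spanning$read_id), , drop = FALSE]
  rownames(spanning) <- NULL

  non_span <- reads[!(reads$read_id %in% spanning$read_id), , drop = FALSE]
  irr <- detect_irrs(non_span, unique(catalog$motif_canonical), params$tau)
  irr <- assign_locus(irr, reads, catalog, params$window_bp)
  irr <- irr[order(irr$sample_id, irr$read_id), , drop = FALSE]
  rownames(irr) <- NULL
  pairs <- find_irr_pairs(irr)

  genotypes <- .genotype_table(spanning, params)

  skip <- c(table(irr$assign_reason[irr$assign_reason != "assigned"]))
  skip_counts <- if (length(skip)) {
    stats::setNames(as.integer(skip), names(skip))
  } else integer(0)
  if (nrow(reads) && any(reads$n_skipped > 0L)) {
    skip_counts["malformed-record"] <- reads$n_skipped[1]
  }
  list(spanning = spanning, irr = irr, irr_pairs = pairs,
       genotypes = genotypes, skip_counts = skip_counts)
}

.genotype_table <- function(spanning, params) {
  empty <- data.frame(sample_id = character(0), locus_id = character(0),
                      allele1 = integer(0), allele2 = integer(0),
                      support1 = integer(0), support2 = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(spanning) == 0L) return(empty)
  groups <- split(spanning$unit_count,
                  paste(spanning$sample_id, spanning$locus_id, sep = "\r"),
                  drop = TRUE)
  rows <- lapply(names(groups), function(nm) {
    g <- genotype_sample(groups[[nm]], params$min_support, params$minor_frac)
    if (is_excluded(g)) return(NULL)
    parts <- strsplit(nm, "\r", fixed = TRUE)[[1]]
    data.frame(sample_id = parts[1], locus_id = parts[2],
               allele1 = g$alleles[1], allele2 = g$alleles[2],
               support1 = g$support[1], support2 = g$support[2],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
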