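# Shared fixtures, all built in code.

# Small clean configuration: no sequencing error, no stutter, no mosaicism.
clean_config <- function(...) {
  sim_config(error_rate = 0, stutter_prob = 0,
             somatic_rate = function(a) 0,
             germline_rate = function(a, d) 0, ...)
}

# A hand-built catalog entry with simple flanks (no repeat-like content).
toy_entry <- function(motif = "CAG", ref_units = 10L) {
  left <- strrep("TGTCA", 12)   # 60 bp
  right <- strrep("TTCAG", 12)  # deliberately contains repeat-like 'CAG'
  right_clean <- strrep("TCTGA", 12)
  list(locus_id = "L1", chrom = "chr1", start = 1000L,
       end = 1000L + ref_units * nchar(motif), motif = motif,
       ref_units = ref_units, left_flank = left,
       right_flank = right_clean,
       motif_canonical = canonicalize_motif(motif))
}

# Build a perfect spanning read: full left flank tail + repeat + right flank
# head, as one string.
spanning_read <- function(entry, units, flank_bp = 20L,
                          interrupt = NULL) {
  la <- substr(entry$left_flank, nchar(entry$left_flank) - flank_bp + 1L,
               nchar(entry$left_flank))
  tract <- strrep(entry$motif, units)
  if (!is.null(interrupt)) {
    k <- nchar(entry$motif)
    i <- interrupt$unit
    substr(tract, (i - 1L) * k + 1L, i * k) <- interrupt$obs
  }
  ra <- substr(entry$right_flank, 1L, flank_bp)
  paste0(la, tract, ra)
}

# Minimal read-record table for constructed reads.
read_table <- function(seqs, sample_id = "S1", chrom = "chr1",
                       pos = 990L, mate_pos = 1200L,
                       qual = NULL) {
  n <- length(seqs)
  if (is.null(qual)) qual <- strrep("F", nchar(seqs))  # Q37
  data.frame(
    read_id = paste0("r", seq_len(n), "/1"),
    fragment_id = paste0("r", seq_len(n)),
    mate_index = 1L, flag = 99L, chrom = chrom,
    pos = rep_len(pos, n), mapped = TRUE, strand = "+",
    mate_chrom = chrom, mate_pos = rep_len(mate_pos, n),
    seq = seqs, qual = qual, sample_id = sample_id, n_skipped = 0L,
    stringsAsFactors = FALSE
  )
}
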