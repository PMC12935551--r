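test_that("detect_irrs classifies reads by best motif and threshold", {
  reads <- read_table(c(
    substr(strrep("AAAG", 40), 1, 151),   # pure AAAG tiling
    substr(strrep("CAG", 51), 1, 151),    # pure CAG tiling
    paste(rep(c("A", "C", "G", "T"), length.out = 151), collapse = "")
  ))
  calls <- detect_irrs(reads, c("CAG", "AAAG"), tau = 0.95)
  expect_equal(nrow(calls), 2L)
  expect_identical(calls$motif[calls$read_id == "r1/1"], "AAAG")
  expect_identical(calls$motif[calls$read_id == "r2/1"], "AGC")
  expect_equal(calls$purity_value, c(1, 1))
})

test_that("assign_locus uses the mate window and records reasons", {
  cat_df <- data.frame(
    locus_id = c("L1", "L2", "L3"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 5000L, 1000L),
    end = c(1030L, 5030L, 1030L),
    motif = "CAG", ref_units = 10L,
    left_flank = strrep("TGTCA", 12), right_flank = strrep("TCTGA", 12),
    motif_canonical = "AGC", stringsAsFactors = FALSE
  )
  mk <- function(mate_pos, mate_chrom = "chr1", mapped_mate = TRUE) {
    r <- read_table(substr(strrep("CAG", 51), 1, 151), chrom = mate_chrom,
                    mate_pos = mate_pos)
    r$mate_chrom <- if (mapped_mate) mate_chrom else NA_character_
    if (!mapped_mate) r$mate_pos <- NA_integer_
    r
  }
  # mate 200 bp left of L1 tract (interval [1230,1381) vs [1000,1030))
  reads <- mk(1230L)
  irr <- assign_locus(detect_irrs(reads, "CAG", 0.95), reads, cat_df, 500L)
  expect_identical(irr$assigned_locus, "L1")
  expect_equal(irr$assignment_distance, 200L)
  # mate 2000 bp away -> outside window
  reads <- mk(3030L)
  irr <- assign_locus(detect_irrs(reads, "CAG", 0.95), reads, cat_df, 500L)
  expect_true(is.na(irr$assigned_locus))
  expect_identical(irr$assign_reason, "no-locus-in-window")
  # two same-motif loci in window -> ambiguous
  wide <- cat_df; wide$start[2] <- 1600L; wide$end[2] <- 1630L
  reads <- mk(1400L)
  irr <- assign_locus(detect_irrs(reads, "CAG", 0.95), reads, wide, 500L)
  expect_identical(irr$assign_reason, "ambiguous")
  # unmapped mate
  reads <- mk(1230L, mapped_mate = FALSE)
  irr <- assign_locus(detect_irrs(reads, "CAG", 0.95), reads, cat_df, 500L)
  expect_identical(irr$assign_reason, "mate-unmapped")
  # never across motif classes: an AT locus cannot take a CAG IRR
  at_cat <- cat_df[1, ]; at_cat$motif <- "AT"; at_cat$motif_canonical <- "AT"
  reads <- mk(1230L)
  irr <- assign_locus(detect_irrs(reads, "CAG", 0.95), reads, at_cat, 500L)
  expect_identical(irr$assign_reason, "no-locus-in-window")
})

test_that("find_irr_pairs requires both mates and unique anchoring", {
  base <- data.frame(
    read_id = c("f1/1", "f1/2", "f2/1", "f3/1", "f3/2"),
    fragment_id = c("f1", "f1", "f2", "f3", "f3"),
    mate_index = c(1L, 2L, 1L, 1L, 2L),
    sample_id = "S1", motif = "AGC", purity_value = 1,
    assigned_locus = c("L1", NA, "L1", NA, NA),
    assignment_distance = NA_integer_,
    assign_reason = c("assigned", "mate-unmapped", "assigned",
                      "mate-unmapped", "mate-unmapped"),
    stringsAsFactors = FALSE
  )
  pairs <- find_irr_pairs(base)
  expect_equal(nrow(pairs), 2L)  # f1 and f3; f2 has a single IRR
  expect_setequal(pairs$fragment_id, c("f1", "f3"))
  expect_true(all(pairs$assigned_locus == "L1"))
  # anchored IRRs at two loci -> ambiguous
  two <- base
  two$assigned_locus[3] <- "L2"
  pairs <- find_irr_pairs(two)
  expect_true(all(pairs$assigned_locus == "ambiguous"))
})

test_that("call_spanning measures units, interruptions and orientation", {
  entry <- toy_entry("CAG", 10L)
  read <- spanning_read(entry, 10L)
  call <- call_spanning(read, NULL, entry, min_anchor_bp = 10L)
  expect_equal(call$unit_count, 10L)
  expect_equal(nrow(call$interruptions), 0L)
  expect_equal(call$bp_length, 30L)
  expect_identical(call$orientation, "+")
  # repeat_end_offset: 20 bp flank + 30 bp tract
  expect_equal(call$repeat_end_offset, 50L)

  # the classic stabilized allele: 18 units with unit 9 reading CAT
  read18 <- spanning_read(entry, 18L, interrupt = list(unit = 9L,
                                                       obs = "CAT"))
  call <- call_spanning(read18, NULL, entry, min_anchor_bp = 10L)
  expect_equal(call$unit_count, 18L)
  expect_equal(call$interruptions$unit_index, 9L)
  expect_identical(call$interruptions$observed, "CAT")

  # reverse-complemented read gives the same call, orientation "-"
  rc <- call_spanning(revcomp(read18), NULL, entry, min_anchor_bp = 10L)
  expect_equal(rc$unit_count, 18L)
  expect_identical(rc$orientation, "-")
  expect_equal(rc$interruptions$unit_index, 9L)

  # left flank + repeat only (no right anchor) -> no call
  la <- substr(entry$left_flank, 41, 60)
  expect_null(call_spanning(paste0(la, strrep("CAG", 12)), NULL, entry))
  # anchors shorter than configured minimum -> configuration error
  short <- entry; short$left_flank <- "ACGTACGT"
  expect_error(call_spanning(read, NULL, short, min_anchor_bp = 10L),
               "min_anchor_bp")
})

test_that("too many interrupted units invalidates a spanning call", {
  entry <- toy_entry("CAG", 12L)
  read <- spanning_read(entry, 12L)
  for (u in c(2L, 5L, 8L, 11L)) {
    k <- nchar(entry$motif)
    off <- 20L + (u - 1L) * k
    substr(read, off + 1L, off + 3L) <- "TTT"
  }
  expect_null(call_spanning(read, NULL, entry, min_anchor_bp = 10L,
                            max_interrupted_units = 3L))
})

test_that("genotype_sample applies support and minor-fraction rules", {
  counts <- c(rep(10L, 14), rep(17L, 12), 11L)
  g <- genotype_sample(counts, min_support = 2L, minor_frac = 0.2)
  expect_equal(g$alleles, c(10L, 17L))
  expect_equal(g$support, c(14L, 12L))
  g <- genotype_sample(rep(10L, 20))
  expect_equal(g$alleles, c(10L, 10L))
  # 2 < max(2, 0.2 * 20) = 4 -> homozygous, 11 left as candidate somatic
  g <- genotype_sample(c(rep(10L, 20), 11L, 11L))
  expect_equal(g$alleles, c(10L, 10L))
  expect_true(is_excluded(genotype_sample(c(10L), min_support = 2L)))
  # read-order invariance
  set.seed(3)
  shuffled <- sample(counts)
  expect_equal(genotype_sample(shuffled), genotype_sample(counts))
})

test_that("harvest output is independent of read order", {
  cfg <- clean_config()
  pop <- simulate_population(cfg, 4, seed = 21)
  sim <- simulate_reads(pop, cfg, seed = 22)
  h1 <- harvest_reads(sim$reads, sim$locus$catalog)
  set.seed(99)
  perm <- sim$reads[sample(nrow(sim$reads)), , drop = FALSE]
  rownames(perm) <- NULL
  h2 <- harvest_reads(perm, sim$locus$catalog)
  expect_equal(h1$spanning, h2$spanning)
  expect_equal(h1$genotypes, h2$genotypes)
  expect_equal(h1$irr, h2$irr)
})

test_that("spanning and IRR calls are mutually exclusive per read", {
  cfg <- clean_config()
  pop <- data.frame(sample_id = "S00001", allele1 = 18L, allele2 = 120L,
                    age = 50, group_id = "120", stringsAsFactors = FALSE)
  sim <- simulate_reads(pop, cfg, seed = 30)
  h <- harvest_reads(sim$reads, sim$locus$catalog)
  expect_length(intersect(h$spanning$read_id, h$irr$read_id), 0L)
})
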