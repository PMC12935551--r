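# -- synthetic data generator -------------------------------------------------
# Ground truth for every stage: a synthetic repeat locus with long unique
# flanks, diploid individuals with configurable allele spectra, age-dependent
# single-step somatic mosaicism, IBD clusters mutating per meiosis, and
# 151 bp paired-end reads (spanning / partial / in-repeat, with IRR pairs)
# carrying i.i.d. substitution errors and PCR-stutter events with their
# polyclonal-cluster base-quality signature.  Every stochastic operation
# takes an explicit seed and is bit-reproducible.

#' Simulation configuration
#'
#' Defaults describe a biobank-style short-read experiment at a polymorphic CAG
#' repeat: 151 bp paired reads, ~16x haploid depth, 450 +/- 100 bp
#' fragments, common alleles of 12-25 units, germline rates rising
#' exponentially with allele length, somatic +1 mosaicism accumulating
#' linearly with age, Q37 baseline qualities and a 2% per-read stutter
#' probability with severely degraded signature qualities.
#'
#' @param motif Repeat unit in reference orientation (default "CAG").
#' @param ref_units Reference allele length in units (default 18).
#' @param flank_len Unique flank length on each side of the tract in bp
#'   (default 800; must exceed fragment mean + 3 sd).
#' @param allele_dist Named numeric vector: allele unit lengths ->
#'   probabilities.
#' @param germline_rate Function(a, direction) -> per-meiosis mutation
#'   probability for a one-unit change in \code{direction} (+1/-1).
#' @param somatic_rate Function(a) -> per-year fraction of cells gaining +1
#'   unit.
#' @param read_length Read length R (default 151).
#' @param haploid_depth Haploid read coverage (default 16; read-start
#'   density c = depth / R).
#' @param frag_mean,frag_sd Fragment-length normal parameters (default
#'   450/100, truncated below at R).
#' @param error_rate Per-base substitution error rate (default 1e-3).
#' @param stutter_prob Per repeat-overlapping read stutter probability
#'   (default 0.02).
#' @param stutter_q_mean,stutter_q_sd Degraded Phred distribution at
#'   signature positions (default 12/4, clipped to [2, base_q]).
#' @param base_q Baseline Phred quality (default 37).
#' @param age_range Uniform age range (default 40-70 years).
#' @param locus_seed Seed for the fixed locus/flank sequences (default 777),
#'   kept separate from per-run seeds so the locus is stable across runs.
#' @return A validated configuration list.
#' @export
sim_config <- function(motif = "CAG",
                       ref_units = 18L,
                       flank_len = 800L,
                       allele_dist = c("12" = 0.20, "15" = 0.25,
                                       "17" = 0.25, "18" = 0.20,
                                       "25" = 0.10),
                       germline_rate = default_germline_rate,
                       somatic_rate = default_somatic_rate,
                       read_length = 151L,
                       haploid_depth = 16,
                       frag_mean = 450,
                       frag_sd = 100,
                       error_rate = 1e-3,
                       stutter_prob = 0.02,
                       stutter_q_mean = 12,
                       stutter_q_sd = 4,
                       base_q = 37L,
                       age_range = c(40, 70),
                       locus_seed = 777L) {
  .check_motif(motif)
  stopifnot(ref_units >= 1, flank_len > frag_mean + 3 * frag_sd,
            abs(sum(allele_dist) - 1) < 1e-8,
            read_length > 0, haploid_depth > 0,
            frag_mean > read_length,
            error_rate >= 0, error_rate <= 1,
            stutter_prob >= 0, stutter_prob <= 1)
  list(motif = motif, ref_units = as.integer(ref_units),
       flank_len = as.integer(flank_len), allele_dist = allele_dist,
       germline_rate = germline_rate, somatic_rate = somatic_rate,
       read_length = as.integer(read_length),
       haploid_depth = haploid_depth, frag_mean = frag_mean,
       frag_sd = frag_sd, error_rate = error_rate,
       stutter_prob = stutter_prob, stutter_q_mean = stutter_q_mean,
       stutter_q_sd = stutter_q_sd, base_q = as.integer(base_q),
       age_range = age_range, locus_seed = as.integer(locus_seed))
}

#' Default length-dependent germline mutation rate
#'
#' Expansion rate 10^(-4 + 0.05 (a - 10)) per meiosis (capped at 0.05),
#' contraction a third of that — instability rising exponentially with
#' allele length and a 3:1 expansion:contraction asymmetry, the shape seen
#' for unstable trinucleotide repeats.
#'
#' @param a Allele length in units.
#' @param direction +1 or -1.
#' @return Per-meiosis probability.
#' @export
default_germline_rate <- function(a, direction) {
  r <- pmin(0.05, 10^(-4 + 0.05 * (a - 10)))
  if (direction > 0) r else r / 3
}

#' Default length-dependent somatic expansion rate
#'
#' Per-year fraction of blood cells gaining one unit:
#' 2e-4 * 10^(0.05 (a - 25)), capped at 0.02/yr — about 1% expanded cells by
#' age 50 for a 25-unit allele.
#'
#' @param a Allele length in units.
#' @return Per-year rate.
#' @export
default_somatic_rate <- function(a) {
  pmin(0.02, 2e-4 * 10^(0.05 * (a - 25)))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build the fixed synthetic locus
#'
#' Generates the locus flanks from \code{config$locus_seed} (so the same
#' config always yields the same reference) and returns the locus geometry
#' plus a single-row catalog.  Flanks are rejected and redrawn in 50 bp
#' windows if they accidentally contain the repeat motif, keeping anchors
#' unambiguous.
#'
#' @param config A \code{\link{sim_config}} list.
#' @return List: \code{catalog} (1-row catalog data.frame, 200 bp flank
#'   columns), \code{contig}, \code{left_ref}, \code{right_ref},
#'   \code{tract_start}, \code{ref_tract_end}, \code{k}, \code{ref_len},
#'   \code{seqinfo}.
#' @export
sim_locus <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$locus_seed)
  k <- nchar(config$motif)
  draw_flank <- function() {
    s <- .random_dna(config$flank_len)
    # keep flanks free of the motif (any rotation / strand)
    bad <- c(rotations(config$motif), rotations(revcomp(config$motif)))
    for (b in unique(bad)) s <- gsub(strrep(b, 2), .random_dna(2L * k), s)
    s
  }
  left_ref <- draw_flank()
  right_ref <- draw_flank()
  tract_start <- config$flank_len
  ref_tract_end <- tract_start + config$ref_units * k
  ref_len <- 2L * config$flank_len + config$ref_units * k
  catalog <- data.frame(
    locus_id = "locus1", chrom = "chrS",
    start = tract_start, end = ref_tract_end,
    motif = config$motif, ref_units = config$ref_units,
    left_flank = substr(left_ref, config$flank_len - 199L,
                        config$flank_len),
    right_flank = substr(right_ref, 1L, 200L),
    stringsAsFactors = FALSE
  )
  catalog$motif_canonical <- canonicalize_motif(config$motif)
  list(catalog = catalog, contig = "chrS", left_ref = left_ref,
       right_ref = right_ref, tract_start = tract_start,
       ref_tract_end = ref_tract_end, k = k, ref_len = ref_len,
       seqinfo = stats::setNames(ref_len, "chrS"))
}

#' Simulate a diploid population at the locus
#'
#' Alleles are drawn i.i.d. from the configured distribution, ages uniformly
#' from the configured range.  The inherited-allele group label (the
#' stand-in for an imputed haplotype group) is the sample's longer allele.
#'
#' @param config \code{\link{sim_config}} list.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return data.frame: \code{sample_id}, \code{allele1 <= allele2},
#'   \code{age}, \code{group_id}.
#' @export
simulate_population <- function(config, n, seed) {
  set.seed(seed)
  if (n == 0L) {
    return(data.frame(sample_id = character(0), allele1 = integer(0),
                      allele2 = integer(0), age = numeric(0),
                      group_id = character(0), stringsAsFactors = FALSE))
  }
  lens <- as.integer(names(config$allele_dist))
  a1 <- lens[sample.int(length(lens), n, replace = TRUE,
                        prob = config$allele_dist)]
  a2 <- lens[sample.int(length(lens), n, replace = TRUE,
                        prob = config$allele_dist)]
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    allele1 = lo, allele2 = hi,
    age = round(stats::runif(n, config$age_range[1], config$age_range[2])),
    group_id = as.character(hi),
    stringsAsFactors = FALSE
  )
}

#' Somatic mosaic mixture for one individual
#'
#' Single-step model: by age t a fraction f = somatic_rate(a) * t of cells
#' carries a + 1 units, the remainder the inherited a (clipped at 1 with a
#' warning).  Deterministic given the genotype and age.
#'
#' @param alleles Integer vector of the two inherited alleles.
#' @param age Age in years.
#' @param config \code{\link{sim_config}} list.
#' @return data.frame: \code{hap}, \code{length_units}, \code{fraction};
#'   fractions sum to 1 within each haplotype.
#' @export
simulate_mosaic <- function(alleles, age, config) {
  rows <- lapply(seq_along(alleles), function(h) {
    a <- alleles[h]
    f <- config$somatic_rate(a) * age
    if (f > 1) {
      warning("somatic fraction clipped to 1 for allele ", a)
      f <- 1
    }
    if (f > 0) {
      data.frame(hap = h, length_units = c(a, a + 1L),
                 fraction = c(1 - f, f))
    } else {
      data.frame(hap = h, length_units = a, fraction = 1)
    }
  })
  do.call(rbind, rows)
}

.revcomp_vec <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Map a molecule coordinate to a reference coordinate: positions inside a
# non-reference-length tract pile at the tract start (as an aligner piles
# pure-repeat reads), positions right of the tract shift by the length
# difference.
.map_pos <- function(pos, tract_start, tract_end_mol, len_diff_bp) {
  ifelse(pos < tract_start, pos,
         ifelse(pos < tract_end_mol, tract_start, pos - len_diff_bp))
}

#' Simulate paired-end reads over the locus for a population
#'
#' For every individual, haplotype and mosaic mixture component, fragment
#' starts form a uniform process at density
#' \code{fraction * haploid_depth / (2 R)} over the molecule; each fragment
#' yields a forward read at its 5' end and a reverse-complemented read at
#' its 3' end.  Reads are classified against their molecule's tract
#' geometry (spanning: covers the tract with >= 10 bp flank both sides;
#' IRR: wholly inside the tract; else partial).  With probability
#' \code{stutter_prob}, a read overlapping the tract is re-extracted from a
#' molecule one unit longer or shorter (left-anchored for forward reads,
#' 3'-end-anchored for reverse reads, as bridge amplification dictates) and
#' every position where the two molecular species disagree gets a degraded
#' quality — the polyclonal-cluster signature.  Substitution errors are
#' i.i.d.; baseline qualities are constant Q\code{base_q}.
#'
#' @param population data.frame from \code{\link{simulate_population}}
#'   (columns \code{sample_id}, \code{allele1}, \code{allele2}, \code{age}).
#' @param config \code{\link{sim_config}} list.
#' @param seed Integer seed.
#' @param sam_path Optional path; when given, reads are also written as SAM
#'   text.
#' @return List: \code{reads} (read-record table in
#'   \code{\link{read_alignments}} schema plus \code{mate_strand},
#'   \code{tlen}), \code{truth} (per-read: \code{read_id},
#'   \code{sample_id}, \code{hap}, \code{source_len_units}, \code{class},
#'   \code{stutter}, \code{stutter_delta}), \code{mixtures} (per-sample
#'   truth mixtures), \code{locus} (from \code{\link{sim_locus}}).
#' @export
simulate_reads <- function(population, config, seed, sam_path = NULL) {
  set.seed(seed)
  loc <- sim_locus(config)
  k <- loc$k
  R <- config$read_length
  c_frag <- config$haploid_depth / (2 * R)
  mol_cache <- new.env(parent = emptyenv())
  molecule <- function(len_units) {
    key <- as.character(len_units)
    if (is.null(mol_cache[[key]])) {
      mol_cache[[key]] <- paste0(loc$left_ref,
                                 strrep(config$motif, len_units),
                                 loc$right_ref)
    }
    mol_cache[[key]]
  }

  read_rows <- list()
  truth_rows <- list()
  mix_rows <- list()
  for (si in seq_len(nrow(population))) {
    sm <- population[si, ]
    mix <- simulate_mosaic(c(sm$allele1, sm$allele2), sm$age, config)
    mix$sample_id <- sm$sample_id
    mix_rows[[si]] <- mix
    frag_counter <- 0L
    for (ci in seq_len(nrow(mix))) {
      lu <- mix$length_units[ci]
      L_bp <- lu * k
      mol <- molecule(lu)
      region_len <- nchar(mol)
      te_mol <- loc$tract_start + L_bp
      n_frag <- stats::rpois(1, c_frag * mix$fraction[ci] * region_len)
      if (n_frag == 0L) next
      Fl <- pmin(pmax(round(stats::rnorm(n_frag, config$frag_mean,
                                         config$frag_sd)), R), region_len)
      fstart <- sample.int(region_len, n_frag, replace = TRUE) - 1L
      ok <- fstart + Fl <= region_len
      Fl <- Fl[ok]; fstart <- fstart[ok]
      n_frag <- length(fstart)
      if (n_frag == 0L) next
      frag_ids <- sprintf("%s_f%07d", sm$sample_id,
                          frag_counter + seq_len(n_frag))
      frag_counter <- frag_counter + n_frag
      # per-fragment read geometry: read1 at 5' start, read2 at 3' end
      s1 <- fstart
      s2 <- fstart + Fl - R
      seq1 <- substring(mol, s1 + 1L, s1 + R)
      seq2m <- substring(mol, s2 + 1L, s2 + R)  # molecule orientation
      baseline_q <- strrep(intToUtf8(config$base_q + 33L), R)
      qstr1 <- rep(baseline_q, n_frag)
      qstr2m <- rep(baseline_q, n_frag)
      st_flag1 <- logical(n_frag); st_flag2 <- logical(n_frag)
      st_delta1 <- integer(n_frag); st_delta2 <- integer(n_frag)

      overlaps <- function(s) s < te_mol & s + R > loc$tract_start
      ov1 <- which(overlaps(s1))
      ov2 <- which(overlaps(s2))
      hit1 <- ov1[stats::runif(length(ov1)) < config$stutter_prob]
      hit2 <- ov2[stats::runif(length(ov2)) < config$stutter_prob]
      degrade <- function(qstr, dpos) {
        q <- phred_to_int(qstr)
        q[dpos] <- .degraded_q(length(dpos), config)
        int_to_phred(q)
      }
      for (i in hit1) {
        delta <- if (lu <= 1L) 1L else sample(c(-1L, 1L), 1)
        mol_st <- molecule(lu + delta)
        new_seq <- substring(mol_st, s1[i] + 1L, s1[i] + R)
        dpos <- which(utf8ToInt(new_seq) != utf8ToInt(seq1[i]))
        if (length(dpos)) {
          seq1[i] <- new_seq
          qstr1[i] <- degrade(qstr1[i], dpos)
          st_flag1[i] <- TRUE; st_delta1[i] <- delta
        }
      }
      for (i in hit2) {
        delta <- if (lu <= 1L) 1L else sample(c(-1L, 1L), 1)
        mol_st <- molecule(lu + delta)
        e2 <- s2[i] + R
        e2_st <- if (e2 >= te_mol) e2 + delta * k else e2
        s2_st <- e2_st - R
        if (s2_st < 0L || e2_st > nchar(mol_st)) next
        new_seq <- substring(mol_st, s2_st + 1L, e2_st)
        dpos <- which(utf8ToInt(new_seq) != utf8ToInt(seq2m[i]))
        if (length(dpos)) {
          seq2m[i] <- new_seq
          qstr2m[i] <- degrade(qstr2m[i], dpos)
          st_flag2[i] <- TRUE; st_delta2[i] <- delta
        }
      }
      # sequencing errors (qualities unaffected)
      seq1 <- .add_errors(seq1, config)
      seq2m <- .add_errors(seq2m, config)
      seq2 <- .revcomp_vec(seq2m)
      # read2 qualities reported in read orientation (baseline is
      # reversal-invariant; only degraded strings need reversing)
      qstr2 <- qstr2m
      for (i in which(qstr2m != baseline_q)) {
        qstr2[i] <- paste(rev(strsplit(qstr2m[i], "")[[1]]), collapse = "")
      }

      len_diff <- L_bp - config$ref_units * k
      p1 <- .map_pos(s1, loc$tract_start, te_mol, len_diff)
      p2 <- .map_pos(s2, loc$tract_start, te_mol, len_diff)
      classify <- function(s) {
        ifelse(s + 10L <= loc$tract_start & s + R >= te_mol + 10L,
               "spanning",
               ifelse(s >= loc$tract_start & s + R <= te_mol,
                      "irr", "partial"))
      }
      rr <- data.frame(
        read_id = c(paste0(frag_ids, "/1"), paste0(frag_ids, "/2")),
        fragment_id = c(frag_ids, frag_ids),
        mate_index = rep(c(1L, 2L), each = n_frag),
        flag = NA_integer_,
        chrom = loc$contig,
        pos = c(p1, p2),
        mapped = TRUE,
        strand = rep(c("+", "-"), each = n_frag),
        mate_strand = rep(c("-", "+"), each = n_frag),
        mate_chrom = loc$contig,
        mate_pos = c(p2, p1),
        tlen = c(Fl, -Fl),
        seq = c(seq1, seq2),
        qual = c(qstr1, qstr2),
        sample_id = sm$sample_id,
        n_skipped = 0L,
        stringsAsFactors = FALSE
      )
      tr <- data.frame(
        read_id = rr$read_id,
        sample_id = sm$sample_id,
        hap = mix$hap[ci],
        source_len_units = lu,
        class = c(classify(s1), classify(s2)),
        stutter = c(st_flag1, st_flag2),
        stutter_delta = c(st_delta1, st_delta2),
        stringsAsFactors = FALSE
      )
      read_rows[[length(read_rows) + 1L]] <- rr
      truth_rows[[length(truth_rows) + 1L]] <- tr
    }
  }
  reads <- if (length(read_rows)) do.call(rbind, read_rows) else
    cbind(.empty_reads(), mate_strand = character(0), tlen = integer(0))
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(read_id = character(0), sample_id = character(0),
               hap = integer(0), source_len_units = integer(0),
               class = character(0), stutter = logical(0),
               stutter_delta = integer(0), stringsAsFactors = FALSE)
  rownames(reads) <- rownames(truth) <- NULL
  if (!is.null(sam_path)) write_sam(reads, sam_path, loc$seqinfo)
  list(reads = reads, truth = truth,
       mixtures = do.call(rbind, mix_rows), locus = loc)
}

.degraded_q <- function(n, config) {
  pmin(config$base_q,
       pmax(2L, round(stats::rnorm(n, config$stutter_q_mean,
                                   config$stutter_q_sd))))
}

.add_errors <- function(seqs, config) {
  if (config$error_rate <= 0) return(seqs)
  n_err <- stats::rbinom(length(seqs), nchar(seqs), config$error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(ch), n_err[i])
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate IBD-sharing allele clusters with per-meiosis mutation
#'
#' Each cluster draws an ancestral allele from the configured distribution;
#' every member's allele then evolves independently over its branch meioses
#' (+1 with germline_rate(a, +1), -1 with germline_rate(a, -1) per meiosis).
#' Tract lengths are exponential with mean 100/m cM.  The emitted table
#' carries the true per-member branch meioses in a \code{meioses} column.
#'
#' @param config \code{\link{sim_config}} list.
#' @param n_clusters Number of clusters.
#' @param cluster_size Members per cluster (default 2).
#' @param m Total meioses separating a pair through the common ancestor
#'   (each branch gets m / cluster_size; default 10).
#' @param seed Integer seed.
#' @return List: \code{members} (TSV-ready member table with columns
#'   \code{cluster_id}, \code{sample_id}, \code{hap}, \code{allele_units},
#'   \code{interruption_sig}, \code{tract_cm}, \code{meioses}),
#'   \code{truth} (per-cluster ancestral allele and event count).
#' @export
simulate_ibd <- function(config, n_clusters, cluster_size = 2L, m = 10,
                         seed = 1L) {
  set.seed(seed)
  lens <- as.integer(names(config$allele_dist))
  anc <- lens[sample.int(length(lens), n_clusters, replace = TRUE,
                         prob = config$allele_dist)]
  n_branch <- n_clusters * cluster_size
  m_branch <- m / cluster_size
  cluster_of <- rep(seq_len(n_clusters), each = cluster_size)
  allele <- anc[cluster_of]
  n_steps <- floor(m_branch)
  frac_step <- m_branch - n_steps
  for (s in seq_len(n_steps)) {
    up <- config$germline_rate(allele, 1L)
    dn <- config$germline_rate(allele, -1L)
    u <- stats::runif(n_branch)
    allele <- allele + (u < up) - (u >= up & u < up + dn)
  }
  if (frac_step > 0) {
    up <- config$germline_rate(allele, 1L) * frac_step
    dn <- config$germline_rate(allele, -1L) * frac_step
    u <- stats::runif(n_branch)
    allele <- allele + (u < up) - (u >= up & u < up + dn)
  }
  tract <- stats::rexp(n_clusters, rate = m / 100)
  members <- data.frame(
    cluster_id = sprintf("c%06d", cluster_of),
    sample_id = sprintf("c%06d_m%d", cluster_of,
                        rep(seq_len(cluster_size), times = n_clusters)),
    hap = 1L,
    allele_units = allele,
    interruption_sig = "",
    tract_cm = tract[cluster_of],
    meioses = m_branch,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    cluster_id = sprintf("c%06d", seq_len(n_clusters)),
    ancestral_units = anc,
    n_events = as.integer(tapply(allele != anc[cluster_of], cluster_of,
                                 sum)),
    stringsAsFactors = FALSE
  )
  list(members = members, truth = truth)
}

#' Geometry-level IRR-count simulation
#'
#' Places read starts as a uniform process at density \code{c_density} over
#' a molecule carrying a tract of \code{L_bp} and counts reads falling
#' wholly inside the tract — the same placement geometry as
#' \code{\link{simulate_reads}} without sequence construction, for fast
#' replicate studies.  E[count] = c_density * max(0, L_bp - R + 1).
#'
#' @param L_bp Tract length in bp.
#' @param c_density Haploid read-start density (reads per bp).
#' @param read_length Read length R.
#' @param flank_len Flank length on each side (default 800).
#' @param n_rep Number of replicates.
#' @param seed Integer seed.
#' @return Integer vector of IRR counts, one per replicate.
#' @export
simulate_irr_counts <- function(L_bp, c_density, read_length = 151L,
                                flank_len = 800L, n_rep = 1000L, seed = 1L) {
  set.seed(seed)
  region_len <- 2L * flank_len + L_bp
  n <- stats::rpois(n_rep, c_density * region_len)
  vapply(n, function(ni) {
    s <- sample.int(region_len, ni, replace = TRUE) - 1L
    sum(s >= flank_len & s + read_length <= flank_len + L_bp)
  }, integer(1))
}

#' Count-level mosaic read sampler
#'
#' Draws the unit lengths of n attributable spanning reads for an allele
#' with somatic +1 fraction f (each read comes from an expanded cell with
#' probability f) — the count-level counterpart of full read simulation for
#' calibration studies.
#'
#' @param a Inherited allele (units).
#' @param f True expanded-cell fraction.
#' @param n_reads Number of attributable reads.
#' @param seed Integer seed.
#' @return Integer vector of per-read unit lengths (a or a + 1).
#' @export
simulate_attributable_reads <- function(a, f, n_reads, seed) {
  set.seed(seed)
  a + (stats::runif(n_reads) < f)
}
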