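# -- tabular and SAM input/output --------------------------------------------
# All coordinates are 0-based half-open internally (BED convention); SAM
# 1-based positions are converted on ingest and on emit.

#' Read a polymorphic-repeat catalog
#'
#' The catalog is a TSV with header columns
#' \code{locus_id chrom start end motif ref_units left_flank right_flank}.
#' \code{start}/\code{end} are 0-based half-open reference coordinates of the
#' repeat tract; \code{motif} may be given in any rotation/strand and is
#' canonicalized on ingest (the reference-orientation unit is inferred from
#' the tract context at spanning-call time); flanks are reference sequence
#' immediately left/right of the tract (>= 30 bp each).
#'
#' @param path Path to the catalog TSV.
#' @return A data.frame with one row per locus and a \code{motif_canonical}
#'   column added.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  req <- c("locus_id", "chrom", "start", "end", "motif", "ref_units",
           "left_flank", "right_flank")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("catalog missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$ref_units <- as.integer(df$ref_units)
  validate_catalog(df)
  df$motif_canonical <- vapply(df$motif, canonicalize_motif, character(1),
                               USE.NAMES = FALSE)
  df
}

validate_catalog <- function(df) {
  if (any(df$end <= df$start)) stop("catalog: end must exceed start",
                                    call. = FALSE)
  if (any(nchar(df$left_flank) < 30L) || any(nchar(df$right_flank) < 30L)) {
    stop("catalog: flanks must be >= 30 bp", call. = FALSE)
  }
  if (any(duplicated(df$locus_id))) stop("catalog: duplicate locus_id",
                                         call. = FALSE)
  invisible(df)
}

#' Write a repeat catalog TSV
#' @param catalog Catalog data.frame (see \code{\link{read_catalog}}).
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  cols <- c("locus_id", "chrom", "start", "end", "motif", "ref_units",
            "left_flank", "right_flank")
  utils::write.table(catalog[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Deterministic TSV writer used for all pipeline outputs.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, ...)
}

# SAM flag bits used here.
.FLAG_PAIRED <- 1L
.FLAG_UNMAPPED <- 4L
.FLAG_MATE_UNMAPPED <- 8L
.FLAG_REVERSE <- 16L
.FLAG_MATE_REVERSE <- 32L
.FLAG_FIRST <- 64L
.FLAG_SECOND <- 128L

phred_to_int <- function(qual) utf8ToInt(qual) - 33L
int_to_phred <- function(q) intToUtf8(q + 33L)

#' Read alignments into a read-record table
#'
#' Accepts SAM text (parsed directly; SAM is tab-delimited text) or BAM
#' (via \pkg{Rsamtools}, if installed, when the file ends in \code{.bam}).
#' Sample identity comes from the \code{RG:Z:} tag when present, else from
#' \code{sample_id}.
#'
#' @param path SAM or BAM file path.
#' @param sample_id Fallback sample id for records without a read group.
#' @return A data.frame with columns \code{read_id}, \code{fragment_id},
#'   \code{mate_index}, \code{flag}, \code{chrom}, \code{pos} (0-based
#'   leftmost), \code{mapped}, \code{strand}, \code{mate_chrom},
#'   \code{mate_pos} (0-based, NA if mate unmapped), \code{seq}, \code{qual}
#'   (Phred+33 string), \code{sample_id}.
#' @export
read_alignments <- function(path, sample_id = NULL) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    return(.read_bam(path, sample_id))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) return(.empty_reads())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 11L
  n_skipped <- sum(bad)
  if (n_skipped > 0L) {
    warning(n_skipped, " malformed SAM record(s) skipped")
    fields <- fields[!bad]
  }
  if (length(fields) == 0L) return(.empty_reads())
  get <- function(i) vapply(fields, `[[`, character(1), i)
  qname <- get(1)
  flag <- as.integer(get(2))
  rname <- get(3)
  pos1 <- as.integer(get(4))
  rnext <- get(7)
  pnext1 <- as.integer(get(8))
  seq <- get(10)
  qual <- get(11)
  rg <- vapply(fields, function(f) {
    tags <- f[-(1:11)]
    hit <- tags[startsWith(tags, "RG:Z:")]
    if (length(hit)) substring(hit[1], 6L) else NA_character_
  }, character(1))
  if (any(is.na(rg))) {
    if (is.null(sample_id)) {
      stop("records without RG tag and no sample_id supplied", call. = FALSE)
    }
    rg[is.na(rg)] <- sample_id
  }
  mapped <- bitwAnd(flag, .FLAG_UNMAPPED) == 0L
  mate_mapped <- bitwAnd(flag, .FLAG_MATE_UNMAPPED) == 0L
  mate_index <- ifelse(bitwAnd(flag, .FLAG_SECOND) != 0L, 2L, 1L)
  mate_chrom <- ifelse(rnext == "=", rname, rnext)
  data.frame(
    read_id = paste0(qname, "/", mate_index),
    fragment_id = qname,
    mate_index = mate_index,
    flag = flag,
    chrom = ifelse(rname == "*", NA_character_, rname),
    pos = ifelse(mapped, pos1 - 1L, NA_integer_),
    mapped = mapped,
    strand = ifelse(bitwAnd(flag, .FLAG_REVERSE) != 0L, "-", "+"),
    mate_chrom = ifelse(mate_mapped & mate_chrom != "*", mate_chrom,
                        NA_character_),
    mate_pos = ifelse(mate_mapped, pnext1 - 1L, NA_integer_),
    seq = seq,
    qual = qual,
    sample_id = rg,
    n_skipped = n_skipped,
    stringsAsFactors = FALSE
  )
}

.empty_reads <- function() {
  data.frame(read_id = character(0), fragment_id = character(0),
             mate_index = integer(0), flag = integer(0),
             chrom = character(0), pos = integer(0), mapped = logical(0),
             strand = character(0), mate_chrom = character(0),
             mate_pos = integer(0), seq = character(0), qual = character(0),
             sample_id = character(0), n_skipped = integer(0),
             stringsAsFactors = FALSE)
}

.read_bam <- function(path, sample_id) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("BAM input requires the Rsamtools package", call. = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mrnm", "mpos", "seq", "qual"),
    tag = "RG")
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  n <- length(b$qname)
  if (n == 0L) return(.empty_reads())
  rg <- b$tag$RG
  if (is.null(rg)) rg <- rep(NA_character_, n)
  if (any(is.na(rg))) {
    if (is.null(sample_id)) {
      stop("records without RG tag and no sample_id supplied", call. = FALSE)
    }
    rg[is.na(rg)] <- sample_id
  }
  flag <- as.integer(b$flag)
  mapped <- bitwAnd(flag, .FLAG_UNMAPPED) == 0L
  mate_mapped <- bitwAnd(flag, .FLAG_MATE_UNMAPPED) == 0L
  mate_index <- ifelse(bitwAnd(flag, .FLAG_SECOND) != 0L, 2L, 1L)
  data.frame(
    read_id = paste0(b$qname, "/", mate_index),
    fragment_id = b$qname,
    mate_index = mate_index,
    flag = flag,
    chrom = as.character(b$rname),
    pos = ifelse(mapped, b$pos - 1L, NA_integer_),
    mapped = mapped,
    strand = ifelse(bitwAnd(flag, .FLAG_REVERSE) != 0L, "-", "+"),
    mate_chrom = ifelse(mate_mapped, as.character(b$mrnm), NA_character_),
    mate_pos = ifelse(mate_mapped, b$mpos - 1L, NA_integer_),
    seq = as.character(b$seq),
    qual = as.character(b$qual),
    sample_id = rg,
    n_skipped = 0L,
    stringsAsFactors = FALSE
  )
}

#' Write a read-record table as SAM text
#'
#' @param reads Read-record data.frame (simulator output schema: columns
#'   \code{fragment_id}, \code{mate_index}, \code{chrom}, \code{pos},
#'   \code{strand}, \code{mate_pos}, \code{seq}, \code{qual},
#'   \code{sample_id}, \code{tlen}).
#' @param path Output SAM path.
#' @param seqinfo Named integer vector of contig lengths for the @SQ header.
#' @export
write_sam <- function(reads, path, seqinfo) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(seqinfo)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, as.integer(seqinfo[[nm]])),
               con)
  }
  for (s in sort(unique(reads$sample_id))) {
    writeLines(sprintf("@RG\tID:%s\tSM:%s", s, s), con)
  }
  if (nrow(reads) == 0L) return(invisible(path))
  flag <- .FLAG_PAIRED +
    ifelse(reads$strand == "-", .FLAG_REVERSE, 0L) +
    ifelse(reads$mate_strand == "-", .FLAG_MATE_REVERSE, 0L) +
    ifelse(reads$mate_index == 1L, .FLAG_FIRST, .FLAG_SECOND)
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tRG:Z:%s",
                   reads$fragment_id, flag, reads$chrom, reads$pos + 1L,
                   nchar(reads$seq), reads$mate_pos + 1L, reads$tlen,
                   reads$seq, reads$qual, reads$sample_id)
  writeLines(lines, con)
  invisible(path)
}
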