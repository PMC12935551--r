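# -- PCR stutter filter -------------------------------------------------------
# During bridge amplification a slippage error makes a flow-cell cluster
# polyclonal: molecules with and without an extra (or missing) repeat unit
# coexist.  The instrument reports the majority base per cycle, but base
# qualities drop at exactly the positions where the two molecular species
# disagree — the sequence downstream of the shorter species' repeat end.
# Genuine somatic length changes come from monoclonal clusters and show no
# such signature, so a quality drop confined to those positions marks a read
# as a likely PCR artifact.

#' Stutter-filter parameter set
#'
#' @param q_low Absolute Phred floor: a signature-mean at or below this is an
#'   artifact (default 25).
#' @param q_drop Relative drop: signature mean at or below control mean minus
#'   this is an artifact (default 10).
#' @param max_delta Only length changes of up to this many units are
#'   classified (default 1; larger jumps are logged unclassified).
#' @param min_end_clearance Reads whose junction falls within this many bp of
#'   the read end are not assessable (default 10).
#' @return Named parameter list.
#' @export
stutter_params <- function(q_low = 25, q_drop = 10, max_delta = 1L,
                           min_end_clearance = 10L) {
  list(q_low = q_low, q_drop = q_drop, max_delta = as.integer(max_delta),
       min_end_clearance = as.integer(min_end_clearance))
}

.rotate <- function(unit, phase) {
  k <- nchar(unit)
  phase <- phase %% k
  if (phase == 0L) return(unit)
  paste0(substr(unit, phase + 1L, k), substr(unit, 1L, phase))
}

#' Read offsets where a one-unit stutter would leave its quality signature
#'
#' Constructs the two sequences expected downstream of the shorter species'
#' repeat end — (i) the right flank directly and (ii) one extra repeat unit
#' then the right flank — and returns the 0-based read offsets (junction to
#' read end) where the two hypotheses
#' differ, in the read's own orientation (for a reverse-strand match the
#' relevant downstream flank is the reverse complement of the left flank).
#' When the flank itself begins with repeat-like sequence the first
#' differing offset is later than the junction, and in the extreme the set
#' can be empty (the species are locally indistinguishable).
#'
#' @param call A spanning call (list with \code{repeat_unit},
#'   \code{bp_length}, \code{repeat_end_offset}; see
#'   \code{\link{call_spanning}}).
#' @param entry Catalog row supplying \code{right_flank} and \code{motif}.
#' @param delta_units Signed length change (+1 or -1).
#' @param read_len Read length in bp.
#' @return Integer vector of 0-based read offsets (possibly empty, with
#'   attribute \code{reason} when the junction is not contained in the read).
#' @export
signature_positions <- function(call, entry, delta_units, read_len) {
  if (abs(delta_units) != 1L) {
    return(structure(integer(0), reason = "delta-out-of-scope"))
  }
  k <- nchar(call$repeat_unit)
  orient <- if (is.null(call$orientation)) "+" else call$orientation
  if (orient == "+") {
    # read orientation == matched orientation: tract runs into right flank
    end_r <- call$repeat_end_offset
    flank_r <- entry$right_flank
    shorter_len <- if (delta_units > 0L) call$bp_length - k else
      call$bp_length
    cont_unit <- .rotate(call$repeat_unit, shorter_len %% k)
  } else {
    # the read was reverse-complemented to match the reference; in its own
    # orientation (the order base qualities were generated in) the tract
    # runs into the reverse complement of the *left* flank, at phase 0
    rep_start0 <- call$repeat_end_offset - call$bp_length
    end_r <- read_len - rep_start0
    flank_r <- revcomp(entry$left_flank)
    cont_unit <- revcomp(call$repeat_unit)
  }
  # junction = repeat end of the *shorter* species, in read coordinates
  j <- if (delta_units > 0L) end_r - k else end_r
  if (j < 0L || j >= read_len) {
    return(structure(integer(0), reason = "junction-outside-read",
                     junction = j))
  }
  span <- read_len - j
  h_short <- substr(flank_r, 1L, span)
  h_long <- substr(paste0(cont_unit, flank_r), 1L, span)
  n_cmp <- min(nchar(h_short), nchar(h_long))
  if (n_cmp == 0L) return(structure(integer(0), junction = j))
  a <- utf8ToInt(substr(h_short, 1L, n_cmp))
  b <- utf8ToInt(substr(h_long, 1L, n_cmp))
  structure(j + which(a != b) - 1L, junction = j)
}

#' Assess one length-discordant spanning read for PCR stutter
#'
#' Compares mean base quality at the stutter-signature positions with the
#' mean over all other read positions.  Verdict is \code{artifact} when the
#' signature mean is at or below \code{q_low}, or at or below the control
#' mean minus \code{q_drop}; otherwise \code{retained}.  Reads with
#' \code{delta_units == 0}, a jump beyond \code{max_delta}, a junction too
#' close to the read end, or an empty signature set are
#' \code{not-applicable}.
#'
#' @param call Spanning call list (needs \code{unit_count},
#'   \code{repeat_unit}, \code{bp_length}, \code{repeat_end_offset},
#'   \code{orientation}).
#' @param alleles Integer vector of the sample's germline alleles at the
#'   locus (length 2).
#' @param quals Integer Phred qualities in the read's own orientation (the
#'   order in which the instrument generated them).
#' @param entry Catalog row.
#' @param params \code{\link{stutter_params}} list.
#' @return List: \code{delta_units}, \code{signature_positions},
#'   \code{mean_q_signature}, \code{mean_q_control}, \code{verdict}.
#' @export
assess_stutter <- function(call, alleles, quals, entry,
                           params = stutter_params()) {
  d_abs <- abs(call$unit_count - alleles)
  nearest <- alleles[which.min(d_abs)]  # tie -> lower allele (sorted input)
  delta <- call$unit_count - nearest
  na_out <- function() {
    list(delta_units = delta, signature_positions = integer(0),
         mean_q_signature = NA_real_, mean_q_control = NA_real_,
         verdict = "not-applicable")
  }
  if (delta == 0L || abs(delta) > params$max_delta) return(na_out())
  read_len <- length(quals)
  sig <- signature_positions(call, entry, sign(delta), read_len)
  j <- attr(sig, "junction")
  if (!is.null(j) && j > read_len - params$min_end_clearance) {
    return(na_out())
  }
  if (length(sig) == 0L) return(na_out())
  q_sig <- mean(quals[sig + 1L])
  q_ctl <- mean(quals[-(sig + 1L)])
  verdict <- if (q_sig <= params$q_low || q_sig <= q_ctl - params$q_drop) {
    "artifact"
  } else "retained"
  list(delta_units = delta, signature_positions = sig,
       mean_q_signature = q_sig, mean_q_control = q_ctl, verdict = verdict)
}

#' Filter spanning calls for PCR-stutter artifacts
#'
#' Applies \code{\link{assess_stutter}} to every spanning call whose length
#' disagrees with its sample's germline genotype.  Reads matching a germline
#' allele are always retained; discordant reads with verdict
#' \code{retained} survive; \code{artifact} and \code{not-applicable} reads
#' are excluded from somatic estimation but logged in the assessment table.
#'
#' @param spanning Spanning-call data.frame (\code{\link{harvest_reads}}
#'   schema, including \code{repeat_unit}, \code{bp_length},
#'   \code{repeat_end_offset}, \code{orientation}).
#' @param genotypes Genotype data.frame (\code{sample_id}, \code{locus_id},
#'   \code{allele1}, \code{allele2}).
#' @param reads Read-record data.frame (for the quality strings).
#' @param catalog Catalog data.frame.
#' @param params \code{\link{stutter_params}} list.
#' @return List with \code{retained} (spanning rows that enter somatic
#'   estimation, with a \code{delta_units} column) and \code{assessments}
#'   (one row per spanning call: \code{read_id}, \code{locus_id},
#'   \code{sample_id}, \code{delta_units}, \code{n_signature_positions},
#'   \code{mean_q_signature}, \code{mean_q_control}, \code{verdict}).
#' @export
filter_stutter <- function(spanning, genotypes, reads, catalog,
                           params = stutter_params()) {
  n <- nrow(spanning)
  out <- data.frame(
    read_id = spanning$read_id, locus_id = spanning$locus_id,
    sample_id = spanning$sample_id,
    delta_units = NA_integer_, n_signature_positions = NA_integer_,
    mean_q_signature = NA_real_, mean_q_control = NA_real_,
    verdict = rep("no-genotype", n), stringsAsFactors = FALSE
  )
  if (n > 0L) {
    gkey <- paste(genotypes$sample_id, genotypes$locus_id, sep = "\r")
    skey <- paste(spanning$sample_id, spanning$locus_id, sep = "\r")
    gidx <- match(skey, gkey)
    ridx <- match(spanning$read_id, reads$read_id)
    cidx <- match(spanning$locus_id, catalog$locus_id)
    for (i in seq_len(n)) {
      if (is.na(gidx[i])) next
      alleles <- sort(c(genotypes$allele1[gidx[i]],
                        genotypes$allele2[gidx[i]]))
      quals <- phred_to_int(reads$qual[ridx[i]])
      call <- list(unit_count = spanning$unit_count[i],
                   repeat_unit = spanning$repeat_unit[i],
                   bp_length = spanning$bp_length[i],
                   repeat_end_offset = spanning$repeat_end_offset[i],
                   orientation = spanning$orientation[i])
      a <- assess_stutter(call, alleles, quals,
                          as.list(catalog[cidx[i], ]), params)
      out$delta_units[i] <- a$delta_units
      out$n_signature_positions[i] <- length(a$signature_positions)
      out$mean_q_signature[i] <- a$mean_q_signature
      out$mean_q_control[i] <- a$mean_q_control
      out$verdict[i] <- if (a$delta_units == 0L) "concordant" else a$verdict
    }
  }
  keep <- out$verdict %in% c("concordant", "retained")
  retained <- spanning[keep, , drop = FALSE]
  retained$delta_units <- out$delta_units[keep]
  rownames(retained) <- NULL
  list(retained = retained, assessments = out)
}
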