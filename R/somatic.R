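# -- somatic instability phenotypes ------------------------------------------
# Turns filtered spanning-read evidence and IRR counts into somatic
# quantities: the fraction of cells in which an allele has gained (or lost)
# one repeat unit, its trend with age, rough length estimates for alleles
# longer than a read, a fragment-count score for highly expanded alleles,
# and per-individual phenotypes calibrated within inherited-allele groups.

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector \code{c(low, high)}.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Per-allele somatic expansion (or contraction) fraction
#'
#' Estimates the average fraction of cells in which germline allele \code{a}
#' has changed length by one repeat unit, as
#' \code{n_shifted / (n_base + n_shifted)} over retained spanning reads
#' attributable to \code{a}.  A sample is eligible for (a, direction) only if
#' it carries at least one germline copy of \code{a}, has no germline allele
#' equal to \code{a + direction}, and its other allele is far enough from
#' \code{a} for reads to be unambiguously attributable (at least
#' \code{min_gap} units away, except for the exact a/a homozygote, whose
#' fraction is interpreted per allele copy).
#'
#' @param unit_counts Integer vector of retained read lengths (units) for one
#'   sample at one locus.
#' @param alleles The sample's two germline alleles (units).
#' @param a The allele whose instability is being measured.
#' @param direction +1 (expansion) or -1 (contraction).
#' @param min_gap Minimum unit distance of the other allele (default 3).
#' @param conf CI level (default 0.95, Wilson).
#' @return List: \code{n_base}, \code{n_shifted}, \code{fraction},
#'   \code{ci_low}, \code{ci_high}; or an \code{\link{excluded}} marker when
#'   the configuration is ineligible.
#' @export
expansion_fraction <- function(unit_counts, alleles, a, direction = 1L,
                               min_gap = 3L, conf = 0.95) {
  stopifnot(direction %in% c(-1L, 1L))
  if (!(a %in% alleles)) {
    return(excluded("allele-not-carried"))
  }
  other <- alleles[alleles != a]
  target <- a + direction
  if (target %in% alleles) {
    return(excluded("target-is-germline"))
  }
  if (length(other) > 0L) {
    if (any(abs(other - a) < min_gap) || any(other == target)) {
      return(excluded("alleles-too-close"))
    }
  }
  n_base <- sum(unit_counts == a)
  n_shift <- sum(unit_counts == target)
  n <- n_base + n_shift
  if (n == 0L) return(excluded("no-attributable-reads"))
  frac <- n_shift / n
  ci <- wilson_ci(n_shift, n, conf)
  list(n_base = n_base, n_shifted = n_shift, fraction = frac,
       ci_low = ci[1], ci_high = ci[2])
}

#' Pool expansion-fraction counts by allele and age bin
#'
#' Counts are summed before taking the ratio (not averaged over
#' per-individual ratios), which keeps the pooled estimate unbiased under
#' varying coverage; the Wilson CI is computed on the pooled counts.
#'
#' @param estimates data.frame with columns \code{locus_id}, \code{allele},
#'   \code{age}, \code{n_base}, \code{n_shifted}.
#' @param breaks Age-bin breakpoints passed to \code{cut} (right-open).
#' @param conf CI level.
#' @return data.frame per (locus_id, allele, age_bin) with pooled counts,
#'   \code{fraction}, \code{ci_low}, \code{ci_high}; empty bins omitted.
#' @export
pool_by_allele_age <- function(estimates, breaks, conf = 0.95) {
  estimates$age_bin <- as.character(cut(estimates$age, breaks = breaks,
                                        right = FALSE))
  estimates <- estimates[!is.na(estimates$age_bin), , drop = FALSE]
  key <- paste(estimates$locus_id, estimates$allele, estimates$age_bin,
               sep = "\r")
  groups <- split(estimates, key)
  rows <- lapply(groups, function(g) {
    nb <- sum(g$n_base); ns <- sum(g$n_shifted)
    ci <- wilson_ci(ns, nb + ns, conf)
    data.frame(locus_id = g$locus_id[1], allele = g$allele[1],
               age_bin = g$age_bin[1], n_base = nb, n_shifted = ns,
               fraction = ns / (nb + ns), ci_low = ci[1], ci_high = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$locus_id, out$allele, out$age_bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Age trend of a somatic metric
#'
#' Weighted least-squares regression of a per-individual metric on age.
#'
#' @param metric Numeric vector of per-individual metrics.
#' @param age Numeric ages (need at least 3 distinct values).
#' @param weights Optional regression weights (e.g. attributable read
#'   counts); equal weights by default.
#' @param conf CI level.
#' @return List: \code{slope} (per year), \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{p_value} (two-sided), \code{n}.
#' @export
age_trend <- function(metric, age, weights = NULL, conf = 0.95) {
  if (length(unique(age)) < 3L) {
    stop("age_trend needs at least 3 distinct ages", call. = FALSE)
  }
  fit <- stats::lm(metric ~ age, weights = weights)
  cf <- summary(fit)$coefficients
  slope <- cf["age", "Estimate"]
  se <- cf["age", "Std. Error"]
  df <- fit$df.residual
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  list(slope = slope, se = se, ci_low = slope - tq * se,
       ci_high = slope + tq * se, p_value = cf["age", "Pr(>|t|)"],
       n = length(metric))
}

#' Rough length estimate for an allele longer than a read
#'
#' A read lands wholly inside a tract of length L bp at L - R + 1 eligible
#' start positions, so E[IRR count] = c (L - R + 1) for haploid read-start
#' density c; the estimator inverts this to L = (R - 1) + count / c.  With
#' somatic mosaicism the estimate is the cell-averaged expanded-allele
#' length.  Zero IRRs censors the estimate at L < R.
#'
#' @param irr_count Number of IRRs assigned to the locus for the sample.
#' @param c_density Haploid read-start density (starts per bp per
#'   haplotype); must be positive.
#' @param read_length Read length R in bp (default 151).
#' @param motif_len Motif length for the unit conversion (default 3).
#' @return List: \code{irr_count}, \code{censored}, \code{est_length_bp},
#'   \code{est_length_units} (NA when censored).
#' @export
long_allele_length <- function(irr_count, c_density, read_length = 151L,
                               motif_len = 3L) {
  if (!is.numeric(c_density) || c_density <= 0) {
    stop("c_density must be positive", call. = FALSE)
  }
  if (irr_count == 0L) {
    return(list(irr_count = 0L, censored = TRUE,
                est_length_bp = NA_real_, est_length_units = NA_real_))
  }
  bp <- (read_length - 1) + irr_count / c_density
  list(irr_count = irr_count, censored = FALSE, est_length_bp = bp,
       est_length_units = bp / motif_len)
}

#' Expected IRR-pair yield for an allele of given length
#'
#' A read pair is fully in-repeat only when the whole fragment fits inside
#' the tract: a fragment of length F has \code{max(0, L - F + 1)} eligible
#' start positions.  The expectation integrates over the fragment-length
#' distribution: \code{E[pairs] = c_frag * sum_F P(F) max(0, L - F + 1)}.
#'
#' @param L Allele length in bp.
#' @param frag_lengths Fragment lengths (support of the distribution).
#' @param frag_probs Matching probabilities (normalized internally).
#' @param c_frag Haploid fragment-start density (fragments per bp).
#' @return Expected IRR-pair count.
#' @export
expected_pair_yield <- function(L, frag_lengths, frag_probs, c_frag) {
  p <- frag_probs / sum(frag_probs)
  c_frag * sum(p * pmax(0, L - frag_lengths + 1))
}

#' Fragment-count score for a highly expanded allele
#'
#' Normalizes the observed IRR-pair count by the fragment-start density,
#' yielding the estimated number of eligible fragment-start positions — a
#' quantity monotone in the underlying allele length and comparable across
#' samples with different coverage.  When the fragment-length distribution
#' is supplied, the score is also inverted to a length estimate by solving
#' \code{expected_pair_yield(L) = irr_pair_count} for L.
#'
#' @param irr_pair_count Observed IRR pairs at the locus.
#' @param c_frag Haploid fragment-start density (fragments per bp).
#' @param frag_lengths,frag_probs Optional fragment-length distribution for
#'   the length inversion.
#' @return List: \code{score} (eligible-start-positions estimate, 0 when no
#'   pairs), \code{est_length_bp} (NA without a distribution or pairs).
#' @export
fragment_metric <- function(irr_pair_count, c_frag, frag_lengths = NULL,
                            frag_probs = NULL) {
  stopifnot(c_frag > 0)
  score <- irr_pair_count / c_frag
  est <- NA_real_
  if (irr_pair_count > 0 && !is.null(frag_lengths)) {
    p <- frag_probs / sum(frag_probs)
    # E[max(0, L - F + 1)] is continuous and increasing in L; invert by root
    f <- function(L) sum(p * pmax(0, L - frag_lengths + 1)) - score
    upper <- max(frag_lengths) + score + 1
    est <- stats::uniroot(f, lower = min(frag_lengths) - 1,
                          upper = upper)$root
  }
  list(score = score, est_length_bp = est)
}

#' Calibrate a metric within inherited-allele groups
#'
#' Isolates the somatic component of a length metric by normalizing each
#' individual against others sharing the same inherited allele: a group
#' z-score and an inverse-normal transform of within-group ranks (offset
#' (r - 0.5)/n, ties averaged).
#'
#' @param metrics Numeric per-sample metric.
#' @param groups Group labels (inherited-allele groups).
#' @param sample_ids Optional sample ids carried into the output.
#' @param min_group Minimum group size (default 10); smaller groups are
#'   dropped.
#' @return data.frame: \code{sample_id}, \code{group_id}, \code{raw_metric},
#'   \code{group_mean}, \code{group_sd}, \code{z_value}, \code{int_value},
#'   \code{dropped_reason} (NA, \code{small-group} or
#'   \code{zero-variance-group}); dropped samples keep NA statistics.
#' @export
calibrate_by_group <- function(metrics, groups, sample_ids = NULL,
                               min_group = 10L) {
  n <- length(metrics)
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(n))
  out <- data.frame(sample_id = sample_ids, group_id = as.character(groups),
                    raw_metric = metrics, group_mean = NA_real_,
                    group_sd = NA_real_, z_value = NA_real_,
                    int_value = NA_real_, dropped_reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (g in unique(out$group_id)) {
    idx <- which(out$group_id == g)
    if (length(idx) < min_group) {
      out$dropped_reason[idx] <- "small-group"
      next
    }
    v <- out$raw_metric[idx]
    m <- mean(v); s <- stats::sd(v)
    if (s == 0) {
      out$dropped_reason[idx] <- "zero-variance-group"
      next
    }
    out$group_mean[idx] <- m
    out$group_sd[idx] <- s
    out$z_value[idx] <- (v - m) / s
    r <- rank(v, ties.method = "average")
    out$int_value[idx] <- stats::qnorm((r - 0.5) / length(idx))
  }
  out
}

#' Mid-length-allele expansion score from spanning reads
#'
#' The average increase in repeat length across retained spanning reads
#' attributable to inherited allele \code{a}: mean(called length - a) over
#' reads with called length in [a, a + max_delta].  Requires the other
#' germline allele to be at least \code{min_gap} units away (or an exact a/a
#' homozygote).
#'
#' @param unit_counts Retained spanning-read lengths (units).
#' @param alleles The sample's germline alleles.
#' @param a Inherited allele being scored.
#' @param max_delta Maximum shift counted (default 1).
#' @param min_gap Attribution gap (default 3).
#' @return List: \code{mean_shift}, \code{n_reads}; or an
#'   \code{\link{excluded}} marker.
#' @export
midlength_score <- function(unit_counts, alleles, a, max_delta = 1L,
                            min_gap = 3L) {
  if (!(a %in% alleles)) {
    return(excluded("allele-not-carried"))
  }
  other <- alleles[alleles != a]
  if (length(other) > 0L && any(abs(other - a) < min_gap)) {
    return(excluded("alleles-too-close"))
  }
  sel <- unit_counts >= a & unit_counts <= a + max_delta
  if (!any(sel)) return(excluded("no-attributable-reads"))
  list(mean_shift = mean(unit_counts[sel] - a), n_reads = sum(sel))
}

#' Screen an instability phenotype against a covariate
#'
#' Linear-regression slope test of a per-individual phenotype on age or on a
#' 0/1/2 genotype dosage (e.g. a mismatch-repair modifier haplotype), with a
#' configurable significance flag.
#'
#' @param phenotype Numeric per-sample phenotype.
#' @param covariate Numeric covariate (age, or dosage in 0..2).
#' @param threshold Flagging threshold on the two-sided p-value (default
#'   1e-4).
#' @return List: \code{beta}, \code{se}, \code{z}, \code{p_value},
#'   \code{flag}.
#' @export
screen_instability <- function(phenotype, covariate, threshold = 1e-4) {
  if (length(unique(covariate)) < 2L) {
    stop("constant covariate", call. = FALSE)
  }
  fit <- stats::lm(phenotype ~ covariate)
  cf <- summary(fit)$coefficients
  beta <- cf["covariate", "Estimate"]
  se <- cf["covariate", "Std. Error"]
  p <- cf["covariate", "Pr(>|t|)"]
  list(beta = beta, se = se, z = beta / se, p_value = p,
       flag = p < threshold)
}
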