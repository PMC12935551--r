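# -- germline mutation rates from IBD-shared alleles -------------------------
# Haplotypes inherited identical-by-descent from a recent common ancestor
# carry the same repeat allele unless a germline mutation intervened on one
# of the branches.  Counting length discordances among IBD-sharing
# haplotypes, with the ancestral allele imputed by consensus, yields
# per-meiosis expansion and contraction rates for each allele state.
# Interrupted alleles are distinct allele states keyed by
# (length, interruption signature), so interrupted and pure alleles of equal
# length accrue separate rates.

#' Estimate the meioses separating IBD-sharing haplotypes from tract length
#'
#' Under the exponential tract-length model a shared segment of genetic
#' length t cM implies about 100/t meioses through the common ancestor,
#' clamped below at 2 (the closest possible relationship through a common
#' ancestor).  Externally supplied meiosis counts override this estimate.
#'
#' @param tract_cm Positive centimorgan length(s) of the shared tract.
#' @return Estimated total meioses (vectorized).
#' @export
meioses_from_tract <- function(tract_cm) {
  if (any(!is.finite(tract_cm)) || any(tract_cm <= 0)) {
    stop("tract_cm must be positive", call. = FALSE)
  }
  pmax(2, 100 / tract_cm)
}

#' Read an IBD cluster table
#'
#' TSV with header columns
#' \code{cluster_id sample_id hap allele_units interruption_sig tract_cm}
#' and optionally \code{meioses} (per-member branch meioses, overriding the
#' tract-length estimate).
#'
#' @param path Path to the TSV.
#' @return data.frame of cluster members.
#' @export
read_ibd_clusters <- function(path) {
  df <- read_tsv(path, colClasses = c(interruption_sig = "character"))
  req <- c("cluster_id", "sample_id", "hap", "allele_units",
           "interruption_sig", "tract_cm")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("IBD table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$interruption_sig[is.na(df$interruption_sig)] <- ""
  df
}

.allele_state <- function(units, sig) {
  ifelse(is.na(sig) | sig == "", as.character(units),
         paste0(units, "|", sig))
}

#' Impute the ancestral allele of an IBD cluster
#'
#' The ancestral allele is the strict modal allele state among the cluster's
#' members (more-distantly shared haplotypes vote down recent mutations).
#' Ties — including discordant pairs with no third member — leave the
#' cluster unpolarized, unless population allele frequencies are supplied:
#' a tie is then resolved toward the globally more frequent state (germline
#' mutations are rare, so the common allele is almost always ancestral —
#' the haplotype-depth analogue of consulting more-distantly shared
#' haplotypes).  A frequency tie still returns unpolarized.
#'
#' @param states Character vector of member allele states (see
#'   \code{\link{extract_events}}) or an integer vector of allele lengths.
#' @param freqs Optional named numeric vector of population allele-state
#'   frequencies (or counts) used to break modal ties.
#' @return The ancestral state as a string, or NA (unpolarized).
#' @export
impute_ancestral <- function(states, freqs = NULL) {
  states <- as.character(states)
  if (length(states) < 2L) stop("cluster needs >= 2 members", call. = FALSE)
  tab <- table(states)
  top <- max(tab)
  modes <- names(tab)[tab == top]
  if (length(modes) == 1L) return(modes)
  if (!is.null(freqs)) {
    f <- freqs[modes]
    f[is.na(f)] <- 0
    best <- which(f == max(f))
    if (length(best) == 1L) return(modes[best])
  }
  NA_character_
}

.state_units <- function(state) {
  as.integer(sub("\\|.*$", "", state))
}

#' Extract mutation events and exposure from one IBD cluster
#'
#' Each member whose allele state differs from the ancestral one contributes
#' one event with \code{step = allele - ancestral} (in units; a changed
#' interruption signature at unchanged length records step 0 as an
#' interruption event).  Every member contributes its branch meioses as
#' exposure attributed to the ancestral allele, regardless of concordance
#' (for a pairwise cluster each branch gets half the total meioses).
#'
#' @param members data.frame with columns \code{sample_id},
#'   \code{allele_units}, \code{interruption_sig}, and either
#'   \code{meioses} (per member) or \code{tract_cm} (cluster-level, from
#'   which total meioses are estimated and split evenly).
#' @param ancestral Ancestral allele state (from
#'   \code{\link{impute_ancestral}}).
#' @return List: \code{events} (data.frame sample_id, ancestral_state,
#'   ancestral_units, step) and \code{exposure} (allele-meioses attributed
#'   to the ancestral state).
#' @export
extract_events <- function(members, ancestral) {
  if (is.na(ancestral)) stop("ancestral allele undefined", call. = FALSE)
  n <- nrow(members)
  if (!is.null(members$meioses) && !all(is.na(members$meioses))) {
    m_i <- members$meioses
  } else {
    m_i <- rep(meioses_from_tract(members$tract_cm[1]) / n, n)
  }
  states <- .allele_state(members$allele_units, members$interruption_sig)
  anc_units <- .state_units(ancestral)
  disc <- which(states != ancestral)
  events <- data.frame(
    sample_id = members$sample_id[disc],
    ancestral_state = rep(ancestral, length(disc)),
    ancestral_units = rep(anc_units, length(disc)),
    step = members$allele_units[disc] - anc_units,
    stringsAsFactors = FALSE
  )
  list(events = events, exposure = sum(m_i))
}

#' Allele-specific germline expansion and contraction rates
#'
#' Processes a full IBD cluster table: imputes each cluster's ancestral
#' allele (modal state, with ties broken by the population allele-state
#' frequency observed across the whole table), extracts discordance events
#' and allele-meioses exposure, and estimates per-generation rates per
#' (allele state, direction) with exact Poisson 95% CIs.  Events with
#' |step| > 1 are reported in the event table but excluded from the +1/-1
#' rate bins.  Per-member \code{meioses} columns are used for exposure when
#' present; otherwise meioses are estimated from \code{tract_cm}.
#'
#' @param clusters IBD member table (see \code{\link{read_ibd_clusters}}).
#' @param min_haplotypes Allele states observed on fewer ancestral
#'   haplotype-meioses sides than this many member haplotypes are pooled
#'   into the \code{"pooled"} state for reporting (default 25; set 0 to
#'   disable).
#' @param conf CI level (default 0.95).
#' @return List: \code{rates} (data.frame allele_state, allele_units,
#'   direction, events, exposure, rate, ci_low, ci_high),
#'   \code{events} (all events incl. multi-step), \code{n_unpolarized},
#'   \code{total_exposure}.
#' @export
estimate_rates <- function(clusters, min_haplotypes = 25L, conf = 0.95) {
  all_states <- .allele_state(clusters$allele_units,
                              clusters$interruption_sig)
  hap_counts <- table(all_states)
  freqs <- hap_counts / sum(hap_counts)
  idx_groups <- split(seq_len(nrow(clusters)), clusters$cluster_id)
  use_meioses <- !is.null(clusters$meioses) &&
    !all(is.na(clusters$meioses))
  n_grp <- length(idx_groups)
  n_unpol <- 0L
  ev_sample <- character(0); ev_state <- character(0); ev_step <- integer(0)
  ex_state <- character(n_grp); ex_val <- numeric(n_grp)
  n_ex <- 0L
  for (idx in idx_groups) {
    states <- all_states[idx]
    anc <- impute_ancestral(states, freqs)
    if (is.na(anc)) {
      n_unpol <- n_unpol + 1L
      next
    }
    exposure <- if (use_meioses) sum(clusters$meioses[idx]) else
      meioses_from_tract(clusters$tract_cm[idx[1]])
    disc <- idx[states != anc]
    if (length(disc)) {
      ev_sample <- c(ev_sample, clusters$sample_id[disc])
      ev_state <- c(ev_state, rep(anc, length(disc)))
      ev_step <- c(ev_step,
                   clusters$allele_units[disc] - .state_units(anc))
    }
    n_ex <- n_ex + 1L
    ex_state[n_ex] <- anc
    ex_val[n_ex] <- exposure
  }
  ex_state <- ex_state[seq_len(n_ex)]
  ex_val <- ex_val[seq_len(n_ex)]
  events <- data.frame(sample_id = ev_sample, ancestral_state = ev_state,
                       ancestral_units = .state_units(ev_state),
                       step = ev_step, stringsAsFactors = FALSE)
  expo_by_state <- tapply(ex_val, ex_state, sum)

  pool_state <- function(s) {
    if (min_haplotypes > 0L && !is.na(hap_counts[s]) &&
        hap_counts[s] < min_haplotypes) "pooled" else s
  }
  states_seen <- names(expo_by_state)
  rep_state <- vapply(states_seen, pool_state, character(1))
  rate_rows <- list()
  for (rs in unique(rep_state)) {
    members <- states_seen[rep_state == rs]
    exposure <- sum(expo_by_state[members])
    if (exposure <= 0) next
    units <- if (rs == "pooled") NA_integer_ else .state_units(rs)
    for (dir in c(1L, -1L)) {
      n_ev <- sum(events$ancestral_state %in% members & events$step == dir)
      ci <- stats::poisson.test(n_ev, conf.level = conf)$conf.int / exposure
      rate_rows[[length(rate_rows) + 1L]] <- data.frame(
        allele_state = rs, allele_units = units, direction = dir,
        events = n_ev, exposure = exposure, rate = n_ev / exposure,
        ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
    }
  }
  rates <- if (length(rate_rows)) do.call(rbind, rate_rows) else
    data.frame(allele_state = character(0), allele_units = integer(0),
               direction = integer(0), events = integer(0),
               exposure = numeric(0), rate = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               stringsAsFactors = FALSE)
  rates <- rates[order(rates$allele_state, -rates$direction), , drop = FALSE]
  rownames(rates) <- NULL
  list(rates = rates, events = events, n_unpolarized = n_unpol,
       total_exposure = sum(ex_val))
}

#' Allele-frequency-weighted mean rate across alleles
#'
#' @param rates Rate table from \code{\link{estimate_rates}} (one
#'   direction).
#' @param freqs Named numeric vector of allele frequencies keyed by
#'   \code{allele_state}; states absent from \code{freqs} are skipped.
#' @return Weighted mean per-generation rate.
#' @export
locus_mean_rate <- function(rates, freqs) {
  keep <- rates$allele_state %in% names(freqs)
  r <- rates[keep, , drop = FALSE]
  w <- freqs[r$allele_state]
  sum(r$rate * w) / sum(w)
}

#' Fold difference between two mutation rates
#'
#' Ratio of two Poisson rates with a conditional-binomial CI: given the
#' total event count, the events in group a are binomial with success
#' probability \code{p = rate_a X_a / (rate_a X_a + rate_b X_b)}; the exact
#' Clopper-Pearson interval for p maps to an interval for the ratio via
#' \code{ratio = p/(1-p) * X_b/X_a}.
#'
#' @param events_a,exposure_a Events and allele-meioses in the numerator
#'   group.
#' @param events_b,exposure_b Denominator group.
#' @param conf CI level.
#' @return List: \code{ratio}, \code{ci_low}, \code{ci_high}.
#' @export
rate_ratio <- function(events_a, exposure_a, events_b, exposure_b,
                       conf = 0.95) {
  if (events_a + events_b == 0L) {
    stop("rate ratio undefined with zero events in both groups",
         call. = FALSE)
  }
  ratio <- (events_a / exposure_a) / (events_b / exposure_b)
  bt <- stats::binom.test(events_a, events_a + events_b, conf.level = conf)
  p_ci <- bt$conf.int
  scale <- exposure_b / exposure_a
  list(ratio = ratio,
       ci_low = p_ci[1] / (1 - p_ci[1]) * scale,
       ci_high = if (p_ci[2] >= 1) Inf else
         p_ci[2] / (1 - p_ci[2]) * scale)
}
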