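test_that("meioses are estimated from tract length with the floor at 2", {
  expect_equal(meioses_from_tract(10), 10)
  expect_equal(meioses_from_tract(100), 2)   # clamped from 1
  expect_equal(meioses_from_tract(1), 100)
  expect_error(meioses_from_tract(0), "positive")
  expect_error(meioses_from_tract(-3), "positive")
})

test_that("ancestral imputation is the strict mode, ties unpolarized", {
  expect_identical(impute_ancestral(c(18, 18, 18, 19)), "18")
  expect_true(is.na(impute_ancestral(c(18, 19))))
  expect_true(is.na(impute_ancestral(c(18, 18, 19, 19))))
  expect_error(impute_ancestral(18), ">= 2 members")
  # population frequencies break ties toward the common allele
  freqs <- c("18" = 0.95, "19" = 0.05)
  expect_identical(impute_ancestral(c(18, 19), freqs), "18")
  expect_true(is.na(impute_ancestral(c(18, 19),
                                     c("18" = 0.5, "19" = 0.5))))
})

test_that("event extraction books one event per discordant member", {
  members <- data.frame(
    sample_id = paste0("s", 1:4), allele_units = c(18L, 18L, 18L, 19L),
    interruption_sig = "", meioses = 5, tract_cm = 20,
    stringsAsFactors = FALSE
  )
  ev <- extract_events(members, impute_ancestral(c(18, 18, 18, 19)))
  expect_equal(nrow(ev$events), 1L)
  expect_equal(ev$events$step, 1L)
  expect_equal(ev$exposure, 20)
  # concordant cluster: zero events, positive exposure
  members$allele_units <- rep(18L, 4)
  ev <- extract_events(members, "18")
  expect_equal(nrow(ev$events), 0L)
  expect_equal(ev$exposure, 20)
  # multi-step change recorded at its observed step
  members$allele_units <- c(18L, 18L, 18L, 20L)
  ev <- extract_events(members, "18")
  expect_equal(ev$events$step, 2L)
  # pairwise cluster without meioses: tract length -> m/2 per member
  pair <- data.frame(sample_id = c("a", "b"), allele_units = c(18L, 18L),
                     interruption_sig = "", meioses = NA_real_,
                     tract_cm = 10, stringsAsFactors = FALSE)
  ev <- extract_events(pair, "18")
  expect_equal(ev$exposure, 10)  # 100/10 cM = 10 meioses total
})

test_that("interrupted alleles are distinct states with separate rates", {
  clusters <- rbind(
    data.frame(cluster_id = "c1", sample_id = c("a", "b", "c"),
               hap = 1L, allele_units = 18L,
               interruption_sig = c("9:CAT", "9:CAT", "9:CAT"),
               tract_cm = 10, meioses = 4, stringsAsFactors = FALSE),
    data.frame(cluster_id = "c2", sample_id = c("d", "e", "f"),
               hap = 1L, allele_units = c(18L, 18L, 19L),
               interruption_sig = "", tract_cm = 10, meioses = 4,
               stringsAsFactors = FALSE)
  )
  est <- estimate_rates(clusters, min_haplotypes = 0)
  pure_up <- est$rates[est$rates$allele_state == "18" &
                         est$rates$direction == 1L, ]
  int_up <- est$rates[est$rates$allele_state == "18|9:CAT" &
                        est$rates$direction == 1L, ]
  expect_equal(pure_up$events, 1L)
  expect_equal(int_up$events, 0L)
  expect_equal(pure_up$exposure, 12)
  expect_equal(int_up$exposure, 12)
})

test_that("estimate_rates matches hand-computed rates and Poisson CIs", {
  # 50 events over 100,000 allele-meioses -> 5e-4 per generation
  n_conc <- 9950L
  mk <- function(id, a2) {
    data.frame(cluster_id = sprintf("c%05d", id), sample_id = c("x", "y"),
               hap = 1L, allele_units = c(18L, a2), interruption_sig = "",
               tract_cm = 10, meioses = 5, stringsAsFactors = FALSE)
  }
  clusters <- do.call(rbind, c(
    lapply(seq_len(n_conc), mk, a2 = 18L),
    lapply(n_conc + seq_len(50L), mk, a2 = 19L)
  ))
  est <- estimate_rates(clusters, min_haplotypes = 0)
  up <- est$rates[est$rates$allele_state == "18" &
                    est$rates$direction == 1L, ]
  expect_equal(up$events, 50L)
  expect_equal(up$exposure, 1e5)
  expect_equal(up$rate, 5e-4)
  pois_ci <- poisson.test(50)$conf.int / 1e5
  expect_equal(c(up$ci_low, up$ci_high), as.numeric(pois_ci))
  # exposure conservation: every member's meioses are counted
  expect_equal(est$total_exposure, 1e5)
})

test_that("zero events give rate 0 with the exact Poisson upper bound", {
  clusters <- do.call(rbind, lapply(1:100, function(i) {
    data.frame(cluster_id = sprintf("c%03d", i), sample_id = c("x", "y"),
               hap = 1L, allele_units = 18L, interruption_sig = "",
               tract_cm = 10, meioses = 50, stringsAsFactors = FALSE)
  }))
  est <- estimate_rates(clusters, min_haplotypes = 0)
  up <- est$rates[est$rates$direction == 1L, ]
  expect_equal(up$rate, 0)
  expect_equal(up$ci_high * up$exposure, 3.688879, tolerance = 1e-4)
})

test_that("rate_ratio reproduces the fold-difference arithmetic", {
  rr <- rate_ratio(50, 1e5, 1, 2.7e5)
  expect_equal(rr$ratio, 135)
  expect_lt(rr$ci_low, 135)
  expect_gt(rr$ci_high, 135)
  rr <- rate_ratio(10, 1e4, 10, 1e4)
  expect_equal(rr$ratio, 1)
  expect_error(rate_ratio(0, 1e4, 0, 1e4), "zero events")
})

test_that("locus mean rate is allele-frequency weighted", {
  rates <- data.frame(allele_state = c("15", "18"), direction = 1L,
                      rate = c(1e-4, 9e-4), stringsAsFactors = FALSE)
  m <- locus_mean_rate(rates, c("15" = 0.75, "18" = 0.25))
  expect_equal(m, 0.75 * 1e-4 + 0.25 * 9e-4)
})

test_that("simulated expansion/contraction asymmetry is recovered", {
  cfg <- sim_config(allele_dist = c("18" = 1),
                    germline_rate = function(a, d) {
                      if (d > 0) 6e-4 else 2e-4
                    })
  ib <- simulate_ibd(cfg, 4000, cluster_size = 2, m = 10, seed = 77)
  est <- estimate_rates(ib$members, min_haplotypes = 0)
  up <- est$rates[est$rates$allele_state == "18" &
                    est$rates$direction == 1L, ]
  dn <- est$rates[est$rates$allele_state == "18" &
                    est$rates$direction == -1L, ]
  expect_gt(up$rate, dn$rate)
  rr <- rate_ratio(up$events, up$exposure, dn$events, dn$exposure)
  expect_true(rr$ci_low <= 3 && 3 <= rr$ci_high)
})
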