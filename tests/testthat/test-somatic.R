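test_that("expansion_fraction computes shifted-read ratios with Wilson CI", {
  # het 10/17, measuring allele 10, direction +1
  calls <- c(rep(10L, 20), 11L, rep(17L, 15))
  est <- expansion_fraction(calls, c(10L, 17L), 10L, +1L)
  expect_equal(est$fraction, 1 / 21)
  expect_equal(est$n_base, 20L)
  expect_equal(est$n_shifted, 1L)
  expect_equal(c(est$ci_low, est$ci_high), wilson_ci(1, 21))
  expect_lte(est$ci_low, est$fraction)
  expect_gte(est$ci_high, est$fraction)
  # zero shifted reads
  est <- expansion_fraction(rep(10L, 20), c(10L, 17L), 10L, +1L)
  expect_equal(est$fraction, 0)
  # homozygote: per-allele-copy interpretation
  est <- expansion_fraction(c(rep(10L, 40), 11L, 11L), c(10L, 10L),
                            10L, +1L)
  expect_equal(est$fraction, 2 / 42)
  # ineligible: other allele equals a + direction
  est <- expansion_fraction(calls, c(10L, 11L), 10L, +1L)
  expect_true(is_excluded(est))
  expect_identical(est$reason, "target-is-germline")
  # ineligible: alleles adjacent (attribution gap)
  est <- expansion_fraction(calls, c(10L, 12L), 10L, +1L)
  expect_identical(est$reason, "alleles-too-close")
  # contraction direction is symmetric
  est <- expansion_fraction(c(rep(10L, 20), 9L), c(10L, 17L), 10L, -1L)
  expect_equal(est$fraction, 1 / 21)
})

test_that("pooling sums counts before the ratio", {
  est <- data.frame(locus_id = "L1", allele = 10L, age = c(45, 47),
                    n_base = c(20L, 20L), n_shifted = c(1L, 1L))
  pooled <- pool_by_allele_age(est, breaks = c(40, 50, 60))
  expect_equal(nrow(pooled), 1L)
  expect_equal(pooled$fraction, 2 / 42)
  # a single individual pools to itself
  one <- pool_by_allele_age(est[1, ], breaks = c(40, 50))
  expect_equal(one$fraction, 1 / 21)
  # all-zero shifted -> flat zero
  est$n_shifted <- 0L
  pooled <- pool_by_allele_age(est, breaks = c(40, 50))
  expect_equal(pooled$fraction, 0)
})

test_that("age_trend recovers a hand-computed slope", {
  # exact linear points make lm warn about a perfect fit; that is the point
  tr <- suppressWarnings(age_trend(c(0.004, 0.005, 0.006), c(40, 50, 60)))
  expect_equal(tr$slope, 1e-4, tolerance = 1e-10)
  tr <- suppressWarnings(age_trend(rep(0.004, 4), c(40, 50, 60, 70)))
  expect_equal(tr$slope, 0)
  expect_error(age_trend(c(1, 2), c(40, 50)), "3 distinct ages")
})

test_that("long_allele_length inverts the IRR-count expectation", {
  m <- long_allele_length(10L, c_density = 0.2, read_length = 151L,
                          motif_len = 3L)
  expect_equal(m$est_length_bp, 200)
  expect_equal(m$est_length_units, 200 / 3)
  expect_false(m$censored)
  m0 <- long_allele_length(0L, 0.2)
  expect_true(m0$censored)
  expect_true(is.na(m0$est_length_bp))
  expect_error(long_allele_length(5L, 0), "positive")
})

test_that("fragment metric matches the enumeration oracle", {
  # fixed fragment length F: eligible starts = L - F + 1
  expect_equal(expected_pair_yield(500, 450, 1, c_frag = 0.05),
               0.05 * (500 - 450 + 1))
  expect_equal(expected_pair_yield(400, 450, 1, c_frag = 0.05), 0)
  fm <- fragment_metric(0L, c_frag = 0.05)
  expect_equal(fm$score, 0)
  # inversion recovers L from the expected count at fixed F
  pairs <- 0.05 * (700 - 450 + 1)
  fm <- fragment_metric(pairs, c_frag = 0.05, frag_lengths = 450,
                        frag_probs = 1)
  expect_equal(fm$est_length_bp, 700, tolerance = 1e-6)
})

test_that("fragment-pair yield is monotone in allele length", {
  set.seed(19)
  fl <- round(rnorm(200, 450, 100)); fl <- fl[fl > 151]
  pr <- rep(1, length(fl))
  L_grid <- seq(300, 1200, by = 100)
  y <- vapply(L_grid, expected_pair_yield, numeric(1),
              frag_lengths = fl, frag_probs = pr, c_frag = 0.05)
  expect_true(all(diff(y) > 0))
})

test_that("group calibration gives z-scores and rank-based INT values", {
  out <- calibrate_by_group(c(1, 2, 3), rep("g", 3), min_group = 3L)
  expect_equal(out$z_value, c(-1, 0, 1))
  expect_equal(out$int_value[2], 0)  # middle rank: qnorm(0.5)
  expect_equal(out$int_value, qnorm((rank(c(1, 2, 3)) - 0.5) / 3))
  # zero-variance group dropped with a reason
  out <- calibrate_by_group(c(2, 2, 2), rep("g", 3), min_group = 3L)
  expect_true(all(out$dropped_reason == "zero-variance-group"))
  # small groups dropped
  out <- calibrate_by_group(1:3, c("a", "a", "b"), min_group = 3L)
  expect_true(all(out$dropped_reason == "small-group"))
  # within-group z has mean 0 and sd 1; INT monotone in the raw metric
  set.seed(4)
  v <- rnorm(50)
  out <- calibrate_by_group(v, rep("g", 50), min_group = 10L)
  expect_equal(mean(out$z_value), 0, tolerance = 1e-12)
  expect_equal(sd(out$z_value), 1, tolerance = 1e-12)
  expect_equal(order(out$int_value), order(out$raw_metric))
})

test_that("midlength score averages the spanning-read shift", {
  s <- midlength_score(c(20L, 20L, 20L, 21L), c(20L, 28L), 20L)
  expect_equal(s$mean_shift, 0.25)
  s <- midlength_score(rep(20L, 6), c(20L, 28L), 20L)
  expect_equal(s$mean_shift, 0)
  expect_true(is_excluded(midlength_score(c(20L, 21L), c(20L, 21L), 20L)))
})

test_that("midlength score matches simulated mosaic fraction", {
  set.seed(23)
  f <- 0.08
  hits <- 0L
  for (rep in 1:20) {
    reads <- simulate_attributable_reads(20L, f, 200L, seed = rep)
    s <- midlength_score(reads, c(20L, 28L), 20L)
    ci <- wilson_ci(sum(reads == 21L), length(reads))
    if (ci[1] <= f && f <= ci[2]) hits <- hits + 1L
    expect_equal(s$mean_shift, mean(reads - 20L))
  }
  expect_gte(hits, 17L)
})

test_that("screen_instability detects a dosage effect and rejects bad input", {
  set.seed(31)
  dosage <- sample(0:2, 2000, replace = TRUE)
  pheno <- 0.15 * dosage + rnorm(2000)
  sc <- screen_instability(pheno, dosage)
  expect_true(sc$flag)
  expect_gt(sc$z, 3)
  expect_error(screen_instability(pheno, rep(1, 2000)), "constant")
})
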