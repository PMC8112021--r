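test_that("burden statistic is the one-sided hypergeometric tail", {
  expect_identical(burden_statistic(0, 0, 10, 10), 0)
  # 3 case-only carriers among 10+10: P(all three carrier labels are case)
  # enumerated directly from the sampling-without-replacement product
  p_enum <- (10 / 20) * (9 / 19) * (8 / 18)
  expect_equal(burden_statistic(3, 0, 10, 10), -log10(p_enum),
               tolerance = 1e-12)
  # one-sidedness: swapping labels with a > b strictly lowers the statistic
  expect_lt(burden_statistic(0, 3, 10, 10), burden_statistic(3, 0, 10, 10))
  expect_error(burden_statistic(1, 0, 0, 10), class = "vtburden_error")
  # binomial inner statistic agrees with the binomial tail
  expect_equal(burden_statistic(3, 0, 10, 10, statistic = "binomial"),
               -log10(pbinom(2, 3, 0.5, lower.tail = FALSE)),
               tolerance = 1e-12)
})

test_that("permutation p-value converges to the exhaustive-label enumeration", {
  # 5 cases / 5 controls; two case-only carriers with REVEL 0.9 and 0.8
  manifest <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    status = rep(c("case", "control"), each = 5)
  )
  variants <- tibble::tibble(
    variant_id = c("v1", "v2"), chrom = "chr1", pos = c(1L, 2L),
    ref = "A", alt = "G", gene = "G1", consequence = "missense",
    revel = c(0.9, 0.8), splice_score = NA_real_,
    af_gnomad = 0, af_cohort = 1e-04, allele_balance = 0.5,
    frac_samples_dp10 = 1, mappability = 1, caller_pass_fraction = 1,
    variant_type = "SNV"
  )
  carriers <- tibble::tibble(sample_id = c("s01", "s02"), gene = "G1",
                             variant_id = c("v1", "v2"))
  exact <- vt_exhaustive_p(
    has_lgd = c(FALSE, FALSE), revel = c(0.9, 0.8),
    carrier_is_case = c(TRUE, TRUE), nA = 5, nB = 5,
    config = "LGD_plus_DMis"
  )
  got <- variable_threshold_test(carriers, variants, manifest, "G1",
                                 B = 20000L, seed = 123, early_stop = Inf)
  mc_err <- 4 * sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(got$perm_p - exact), mc_err)
  # determinism of the permutation stream
  again <- variable_threshold_test(carriers, variants, manifest, "G1",
                                   B = 2000L, seed = 99)
  expect_identical(
    again$perm_p,
    variable_threshold_test(carriers, variants, manifest, "G1",
                            B = 2000L, seed = 99)$perm_p
  )
})

test_that("anti-enriched and empty genes cannot look significant", {
  manifest <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:20),
    status = rep(c("case", "control"), each = 10)
  )
  variants <- tibble::tibble(
    variant_id = c("v1", "v2"), chrom = "chr1", pos = c(1L, 2L),
    ref = "A", alt = "G", gene = "G1", consequence = "missense",
    revel = c(0.7, 0.6), splice_score = NA_real_,
    af_gnomad = 0, af_cohort = 1e-04, allele_balance = 0.5,
    frac_samples_dp10 = 1, mappability = 1, caller_pass_fraction = 1,
    variant_type = "SNV"
  )
  # both carriers are controls
  carriers <- tibble::tibble(sample_id = c("s11", "s12"), gene = "G1",
                             variant_id = c("v1", "v2"))
  got <- variable_threshold_test(carriers, variants, manifest, "G1",
                                 B = 400L, seed = 7)
  expect_gte(got$perm_p, 0.5)
  # gene with no qualifying variants: p = 1, cutoff undefined
  empty <- variable_threshold_test(carriers[0, ], variants[0, ], manifest,
                                   "G2", B = 100L, seed = 1)
  expect_identical(empty$perm_p, 1)
  expect_true(is.na(empty$optimal_revel_cutoff))
})

test_that("re-maximizing permutations dominate the fixed-cutoff fisher p", {
  cfg <- sim_config(n_cases = 100, n_controls = 400, n_genes = 30, seed = 55,
                    baseline_carrier_freq = 0.02)
  sim <- simulate_case_control_cohort(cfg)
  sc <- genomewide_scan(sim, B = 300, seed = 56, configs = "LGD_plus_DMis")
  res <- sc$results[sc$results$case_carriers + sc$results$control_carriers > 0, ]
  fixed_p <- phyper(res$case_carriers - 1, sc$n_cases, sc$n_controls,
                    res$case_carriers + res$control_carriers,
                    lower.tail = FALSE)
  # selection bias: the naive p at the selected cutoff understates the
  # truth, so the permutation p is stochastically larger
  expect_gt(mean(res$perm_p), mean(fixed_p))
  qs <- c(0.25, 0.5, 0.75)
  expect_true(all(quantile(res$perm_p, qs) >= quantile(fixed_p, qs)))
})

test_that("scan output is coherent and flags nothing on tiny null cohorts", {
  cfg <- sim_config(n_cases = 50, n_controls = 200, n_genes = 12, seed = 70,
                    baseline_carrier_freq = 0.02)
  sim <- simulate_case_control_cohort(cfg)
  sc <- genomewide_scan(sim, B = 200, seed = 71)
  expect_s3_class(sc, "vt_scan")
  expect_identical(sc$n_tests, nrow(sc$results))
  expect_identical(
    sc$n_tests,
    2L * dplyr::n_distinct(sim$variants$gene)
  )
  expect_true(all(sc$results$perm_p >= 1 / 201))
  expect_true(all(sc$results$q_value <= 1))
  expect_true(all(sc$results$case_carriers <= sc$n_cases))
  td <- tidy(sc)
  expect_identical(nrow(td), sc$n_tests)
  gl <- glance(sc)
  expect_identical(gl$n_tests, sc$n_tests)
  # empty cohort degenerates cleanly
  empty <- genomewide_scan(
    list(manifest = sim$manifest,
         variants = sim$variants[0, ], carriers = sim$carriers[0, ]),
    B = 10, seed = 1
  )
  expect_identical(empty$n_tests, 0L)
})

test_that("BH q-values match the brute-force step-up definition", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("Bonferroni threshold arithmetic matches the study conventions", {
  expect_equal(bonferroni_threshold(0.05, 40000), 1.25e-06)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  # the unrounded count of tested genes gives a slightly looser threshold,
  # documenting why the round number 40,000 is the conservative choice
  expect_equal(signif(bonferroni_threshold(0.05, 2 * 18939), 3), 1.32e-06)
})

test_that("genomic-control lambda is calibrated on constructions", {
  n <- 10000
  expect_equal(genomic_control_lambda((1:n) / (n + 1)), 1, tolerance = 0.01)
  set.seed(3)
  inflated <- pchisq(rchisq(n, 1) * 1.3, 1, lower.tail = FALSE)
  lam <- genomic_control_lambda(inflated)
  expect_gt(lam, 1.25)
  expect_lt(lam, 1.35)
  expect_error(genomic_control_lambda(rep(1, 100)), class = "vtburden_error")
  expect_error(genomic_control_lambda(runif(5)), class = "vtburden_error")
})

test_that("synonymous calibration recovers equal and unequal rates", {
  expect_equal(
    synonymous_calibration(rep(40, 100), rep(40, 1000))$rate_ratio, 1
  )
  set.seed(8)
  null_run <- synonymous_calibration(rpois(500, 40), rpois(5000, 40))
  expect_gt(null_run$rate_ratio, 0.97)
  expect_lt(null_run$rate_ratio, 1.03)
  expect_gt(null_run$p_value, 0.001)
  shifted <- synonymous_calibration(rpois(500, 60), rpois(5000, 40))
  expect_lt(shifted$p_value, 0.001)
  expect_gt(shifted$rate_ratio, 1.3)
})

test_that("power calculation matches Monte-Carlo rejection of the z-test", {
  expect_equal(burden_power(100, 1000, 0.01, 1), 0.05)
  expect_gt(burden_power(500, 5000, 0.005, 8, alpha = 1e-04),
            burden_power(500, 5000, 0.005, 4, alpha = 1e-04))
  expect_gt(burden_power(1000, 5000, 0.005, 4, alpha = 1e-04),
            burden_power(500, 5000, 0.005, 4, alpha = 1e-04))
  nA <- 1647; nB <- 18819; freq <- 0.001; rr <- 10; alpha <- 1.25e-06
  set.seed(101)
  reps <- 20000
  a <- rbinom(reps, nA, freq * rr)
  b <- rbinom(reps, nB, freq)
  pp <- (a + b) / (nA + nB)
  z <- (a / nA - b / nB) / sqrt(pp * (1 - pp) * (1 / nA + 1 / nB))
  mc <- mean(z > qnorm(1 - alpha))
  expect_equal(burden_power(nA, nB, freq, rr, alpha), mc, tolerance = 0.02)
  expect_error(burden_power(10, 10, 0.5, 3), class = "vtburden_error")
})
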