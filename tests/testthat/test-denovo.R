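test_that("per-codon class rates equal exhaustive substitution enumeration", {
  rt <- demo_rate_table(base_rate = 1e-08, cpg_boost = 10)
  lookup <- rate_lookup_from(rt)
  for (codon in c("ATG", "TGG", "CTT", "CGA", "TAC")) {
    g <- gene_model_from_seq(paste0("A", codon, "C"))
    got <- gene_class_rates(g, rt, dmis_fraction = 0.2, lgd_factor = 2)
    want <- codon_oracle(codon, "A", "C", lookup)
    expect_equal(got$syn_rate, unname(want["SYN"]), tolerance = 1e-15)
    expect_equal(got$mis_rate, unname(want["MIS"]), tolerance = 1e-15)
    expect_equal(got$non_rate, unname(want["NON"]), tolerance = 1e-15)
    # conservation: the three substitution classes exhaust all 9 changes
    expect_equal(got$total_rate, sum(want), tolerance = 1e-15)
  }
  # TGG (Trp): every change at codon positions 1 and 2 is nonsynonymous
  g <- gene_model_from_seq("ATGGC")
  got <- gene_class_rates(g, rt)
  expect_equal(got$syn_rate, 0)
})

test_that("uniform rates conserve to 9 mu per codon and scale with mappability", {
  rt <- demo_rate_table(base_rate = 2e-08, cpg_boost = 1)
  g <- gene_model_from_seq("AATGC")
  expect_equal(gene_class_rates(g, rt)$total_rate, 9 * 2e-08,
               tolerance = 1e-12)
  g$mappable_fraction <- 0.5
  expect_equal(gene_class_rates(g, rt)$total_rate, 4.5 * 2e-08,
               tolerance = 1e-12)
  zero <- rt; zero$mu <- 0
  expect_equal(gene_class_rates(g, zero)$total_rate, 0)
  expect_error(gene_class_rates(gene_model_from_seq("ANTGC"), rt),
               class = "vtburden_error")
})

test_that("class rates are invariant to how intervals split the gene", {
  g1 <- gene_model_from_seq(paste0("G", strrep("ATGCTTCGA", 20), "T"))
  g2 <- g1
  g2$intervals <- list(tibble::tibble(start = c(100L, 300L),
                                      end = c(190L, 390L)))
  expect_equal(gene_class_rates(g1, demo_rate_table()),
               gene_class_rates(g2, demo_rate_table()))
})

test_that("expected counts are linear in trios and respect gene-set restriction", {
  genes <- simulate_gene_models(6, seed = 3)
  gr <- gene_class_rates(genes, demo_rate_table())
  expect_identical(expected_count(gr, "SYN", 0), 0)
  expect_equal(expected_count(gr, "SYN", 200), 2 * expected_count(gr, "SYN", 100))
  sub <- genes$gene[1:3]
  hand <- 2 * 124 * sum(gr$lgd_dmis_rate[gr$gene %in% sub])
  expect_equal(expected_count(gr, "LGD_plus_DMis", 124, gene_set = sub), hand,
               tolerance = 1e-12)
  expect_equal(
    expected_count(gr, "SYN", 124, gene_set = sub) +
      expected_count(gr, "SYN", 124, exclude = sub),
    expected_count(gr, "SYN", 124),
    tolerance = 1e-12
  )
  expect_error(expected_count(gr, "BOGUS", 10), class = "vtburden_error")
})

test_that("exact Poisson test agrees with the reference implementation", {
  # published observed/expected pairs, at printed precision
  expect_equal(signif(exact_poisson_test(29, 11.85), 2), 2.5e-05)
  expect_equal(signif(exact_poisson_test(19, 7.25), 2), 2.0e-04)
  expect_identical(exact_poisson_test(0, 5, sided = "greater"), 1)
  # dual route: randomized grid against stats::poisson.test
  set.seed(77)
  for (i in 1:40) {
    m0 <- runif(1, 0.5, 60)
    m1 <- rpois(1, m0 * runif(1, 0.3, 3))
    expect_equal(exact_poisson_test(m1, m0),
                 stats::poisson.test(m1, r = m0)$p.value,
                 tolerance = 1e-10)
    expect_equal(exact_poisson_test(m1, m0, sided = "greater"),
                 stats::poisson.test(m1, r = m0,
                                     alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
  expect_error(exact_poisson_test(5, 0), class = "vtburden_error")
  expect_error(exact_poisson_test(2.5, 1), class = "vtburden_error")
})

test_that("two-sided p dominates one-sided for excess counts, both monotone", {
  for (m1 in c(15, 20, 29)) {
    expect_gte(exact_poisson_test(m1, 11.85),
               exact_poisson_test(m1, 11.85, sided = "greater"))
  }
  p_two <- vapply(12:30, exact_poisson_test, numeric(1), m0 = 11.85)
  p_one <- vapply(12:30, exact_poisson_test, numeric(1), m0 = 11.85,
                  sided = "greater")
  expect_true(all(diff(p_two) < 0))
  expect_true(all(diff(p_one) < 0))
})

test_that("burden summary reproduces the published de novo table arithmetic", {
  hle_lgd_dmis <- denovo_burden_summary(29, 11.85, n_trios = 124)
  expect_equal(round(hle_lgd_dmis$enrichment, 2), 2.45)
  expect_identical(hle_lgd_dmis$est_risk_variants, 17L)
  expect_equal(round(denovo_burden_summary(19, 7.25)$enrichment, 2), 2.62)
  expect_identical(denovo_burden_summary(19, 7.25)$est_risk_variants, 12L)
  all_lgd_dmis <- denovo_burden_summary(44, 28.9)
  expect_equal(round(all_lgd_dmis$enrichment, 2), 1.52)
  expect_identical(all_lgd_dmis$est_risk_variants, 15L)
  excl_known <- denovo_burden_summary(22, 11.85)
  expect_equal(round(excl_known$enrichment, 2), 1.86)
  expect_identical(excl_known$est_risk_variants, 10L)
  # degenerate equality
  eq <- denovo_burden_summary(10, 10)
  expect_equal(eq$enrichment, 1)
  expect_identical(eq$est_risk_variants, 0L)
  expect_equal(eq$p_value, 1)
})

test_that("observed-variant counting honors gene sets and exclusions", {
  genes <- simulate_gene_models(8, seed = 12)
  gr <- gene_class_rates(genes, demo_rate_table(base_rate = 1e-05))
  obs <- tibble::tibble(
    gene = genes$gene[c(1, 1, 2, 3, 4, 5)],
    class = c("LGD", "DMis", "SYN", "LGD", "MIS", "DMis")
  )
  all_genes <- denovo_burden(obs, gr, "LGD_plus_DMis", 124)
  expect_identical(all_genes$m1, 4L + 0L) # 2 in gene1, LGD gene3, DMis gene5
  restricted <- denovo_burden(obs, gr, "LGD_plus_DMis", 124,
                              gene_set = genes$gene[1:3])
  expect_identical(restricted$m1, 3L)
  excl <- denovo_burden(obs, gr, "LGD_plus_DMis", 124,
                        exclude = genes$gene[1])
  expect_identical(excl$m1, 2L)
  # exclusion leaves the expectation unchanged unless asked
  expect_equal(excl$m0, all_genes$m0)
  excl2 <- denovo_burden(obs, gr, "LGD_plus_DMis", 124,
                         exclude = genes$gene[1],
                         exclude_from_expected = TRUE)
  expect_lt(excl2$m0, all_genes$m0)
  # MIS counts total missense including the deleterious subset
  expect_identical(denovo_burden(obs, gr, "MIS", 124)$m1, 3L)
  expect_error(denovo_burden(obs, gr, "weird", 124), class = "vtburden_error")
})

test_that("rate-table io validates completeness", {
  rt <- demo_rate_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(rt, path)
  expect_equal(read_rate_table(path), rt)
  expect_error(check_rate_table(rt[-1, ]), class = "vtburden_error")
  bad <- rt; bad$mu[1] <- -1
  expect_error(check_rate_table(bad), class = "vtburden_error")
})
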