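test_that("Hardy-Weinberg genotype frequencies match the worked values", {
  hom <- genotype_spec("homozygous", q1 = 0.003052)
  expect_equal(hw_genotype_frequency(hom), 9.314704e-06, tolerance = 1e-12)
  chet <- genotype_spec("compound_het", q1 = 0.003052, q2 = 0.000383,
                        labels = c("c.783G>A", "c.143C>A"))
  expect_equal(hw_genotype_frequency(chet), 2.337832e-06, tolerance = 1e-12)
  cngb3 <- genotype_spec("homozygous", q1 = 0.004161)
  expect_equal(hw_genotype_frequency(cngb3), 1.7313921e-05, tolerance = 1e-12)
  expect_equal(hw_genotype_frequency(genotype_spec("homozygous", q1 = 0)), 0)
  expect_equal(hw_genotype_frequency(genotype_spec("hemizygous", q1 = 0.01)),
               0.01)
  expect_error(genotype_spec("homozygous", q1 = 1.2), "q1")
  expect_error(genotype_spec("compound_het", q1 = 0.1), "q2")
  expect_error(genotype_spec("compound_het", q1 = 0.1, q2 = 0.2,
                             labels = c("a", "a")), "distinct")
})

test_that("hw frequency is monotone in q and bounded by q", {
  qs <- seq(0, 1, by = 0.05)
  f <- vapply(qs, function(q)
    hw_genotype_frequency(genotype_spec("homozygous", q1 = q)), 1)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f <= qs))
})

test_that("penetrance estimates reproduce the worked cohort numbers", {
  # CNGB3 c.1208G>A homozygotes: 4/1352, prevalence 1/5000
  est <- estimate_penetrance(4, 1352, 1 / 5000, 1.7313921e-05)
  expect_equal(as_percent(est$penetrance), 3.4)
  expect_equal(est$flag, "reduced")
  # CDHR1 c.783G>A homozygotes: 13/1352 -> ~20.6-20.7%
  est <- estimate_penetrance(13, 1352, 1 / 5000, 9.314704e-06)
  expect_lt(abs(100 * est$penetrance - 20.7), 0.1 + 1e-9)
  # CDHR1 compound heterozygotes: 2/1352 -> ~12.6-12.7%
  est <- estimate_penetrance(2, 1352, 1 / 5000, 2.337832e-06)
  expect_lt(abs(100 * est$penetrance - 12.6), 0.1 + 1e-9)
})

test_that("penetrance formula identities hold", {
  # k/n = p_x / prevalence gives exactly 1
  est <- estimate_penetrance(10, 1000, 0.001, 10 / 1000 * 0.001)
  expect_equal(est$penetrance, 1)
  expect_equal(est$flag, "complete")
  # linear in prevalence and observed count; halving p_x doubles it
  base <- estimate_penetrance(5, 1000, 2e-4, 1e-5)$penetrance
  expect_equal(estimate_penetrance(5, 1000, 4e-4, 1e-5)$penetrance, 2 * base)
  expect_equal(estimate_penetrance(10, 1000, 2e-4, 1e-5)$penetrance, 2 * base)
  expect_equal(estimate_penetrance(5, 1000, 2e-4, 5e-6)$penetrance, 2 * base)
})

test_that("degenerate and extreme estimates are flagged, not clamped", {
  expect_equal(estimate_penetrance(0, 1352, 2e-4, 1e-5)$flag, "not_estimable")
  expect_equal(estimate_penetrance(5, 1352, 2e-4, 0)$flag, "not_estimable")
  supra <- estimate_penetrance(100, 1000, 0.01, 1e-5)
  expect_equal(supra$flag, "supra_unity")
  expect_gt(supra$penetrance, 1)  # reported raw
  expect_error(estimate_penetrance(5, 0, 2e-4, 1e-5), "cohort_n")
  expect_error(estimate_penetrance(5, 1000, 0, 1e-5), "prevalence")
})

test_that("reduced-penetrance flagging respects the threshold", {
  est <- estimate_penetrance(4, 1352, 1 / 5000, 1.7313921e-05)
  expect_equal(flag_reduced_penetrance(est), "reduced")
  est <- estimate_penetrance(13, 1352, 1 / 5000, 9.314704e-06)
  expect_equal(flag_reduced_penetrance(est), "reduced")
  full <- estimate_penetrance(10, 1000, 0.001, 10 / 1000 * 0.001)
  expect_equal(flag_reduced_penetrance(full), "complete")
  expect_equal(flag_reduced_penetrance(full, threshold = 1.0000001),
               "reduced")
})

test_that("cohort allele frequency is the exact fraction", {
  expect_equal(as_percent(cohort_allele_frequency(31, 2704), 2), 1.15)
  expect_equal(cohort_allele_frequency(0, 2704), 0)
  expect_error(cohort_allele_frequency(10, 2705), "even")
  expect_error(cohort_allele_frequency(30, 20), "allele_count")
  set.seed(5)
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  for (i in 1:50) {
    n2 <- 2L * sample.int(5000, 1)
    k <- sample.int(n2, 1)
    g <- gcd(k, n2)
    expect_equal(cohort_allele_frequency(k, n2), (k / g) / (n2 / g))
  }
})

test_that("reference table recomputes the flagged-variant estimates", {
  tab <- reference_penetrance_table()
  expect_equal(tab$p_x_pct, c(0.000931, 0.000234, 0.001731))
  expect_equal(tab$penetrance_pct[tab$genotype == "CNGB3 c.1208G>A hom"], 3.4)
  expect_true(all(tab$flag == "reduced"))
  expect_true(all(abs(tab$penetrance_pct - c(20.7, 12.6, 3.4)) <= 0.1))
})

test_that("penetrance is inversely proportional to the assumed prevalence", {
  sweep <- penetrance_prevalence_sweep(13, 1352, 9.314704e-06,
                                       prevalences = 1 / c(2500, 5000, 10000))
  expect_equal(sweep$penetrance[1] / sweep$penetrance[2], 2)
  expect_equal(sweep$penetrance[3] / sweep$penetrance[2], 0.5)
})

test_that("bootstrap interval brackets the point estimate deterministically", {
  ci1 <- penetrance_bootstrap_ci(13, 1352, 1 / 5000, 9.314704e-06, seed = 4)
  ci2 <- penetrance_bootstrap_ci(13, 1352, 1 / 5000, 9.314704e-06, seed = 4)
  expect_identical(ci1$lower, ci2$lower)
  est <- estimate_penetrance(13, 1352, 1 / 5000, 9.314704e-06)$penetrance
  expect_lte(ci1$lower, est)
  expect_gte(ci1$upper, est)
})

test_that("reduced-penetrance census counts flagged carriers among solved", {
  vt <- rbind(
    make_variant("P1", "CDHR1", "c.783G>A", acmg_class = 5L,
                 zygosity = "hom"),
    make_variant("P2", "PROM1", "c.5T>A", acmg_class = 5L, zygosity = "hom"),
    make_variant("P3", "RP1L1", "c.133C>T", acmg_class = 4L,
                 zygosity = "het"),
    make_variant("P4", "CDHR1", "c.783G>A", acmg_class = 5L,
                 zygosity = "het"))
  verdicts <- data.frame(
    proband_id = c("P1", "P2", "P3", "P4"),
    status = c("very_likely_solved", "very_likely_solved",
               "possibly_solved", "unsolved"),
    causal_gene = c("CDHR1", "PROM1", "RP1L1", NA),
    multi_gene = FALSE, rationale = "", stringsAsFactors = FALSE)
  cen <- reduced_penetrance_census(verdicts, vt)
  expect_equal(cen$count, 2)       # P1 and P3; P4 is unsolved
  expect_equal(cen$n_solved, 3)
  expect_equal(cen$share_pct, 66.7)
  empty <- reduced_penetrance_census(verdicts, vt,
                                     flagged = data.frame(gene = character(),
                                                          hgvs_c = character()))
  expect_equal(empty$count, 0)
  # brute-force membership re-count on a random fixture
  genes <- demo_genes()
  rv <- random_variants(500, seed = 12)
  sheet <- data.frame(proband_id = sprintf("P%03d", 1:40), phenotype = "MD",
                      stringsAsFactors = FALSE)
  vd <- assign_verdicts(suppressWarnings(prioritise(rv, genes)), genes, sheet)
  flagged <- default_reduced_penetrance_variants()
  cen <- reduced_penetrance_census(vd, rv, flagged)
  solved_ids <- vd$proband_id[vd$status %in% c("very_likely_solved",
                                               "possibly_solved")]
  manual <- sum(vapply(solved_ids, function(id) {
    pv <- rv[rv$proband_id == id, ]
    any(paste(pv$gene, pv$hgvs_c) %in% paste(flagged$gene, flagged$hgvs_c))
  }, TRUE))
  expect_equal(cen$count, manual)
})
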