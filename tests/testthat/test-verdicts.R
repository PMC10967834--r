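test_that("phase presumption: two distinct rare hets are presumed trans", {
  two_het <- rbind(
    make_variant("P1", "ROM1", "c.339dupG", zygosity = "het",
                 consequence = "frameshift"),
    make_variant("P1", "ROM1", "c.712del", zygosity = "het",
                 consequence = "frameshift"))
  expect_equal(presume_phase(two_het), "presumed_trans")
  # long-read evidence overrides the presumption
  expect_equal(presume_phase(two_het, evidence = "trans"), "trans")
  expect_equal(presume_phase(two_het, evidence = "cis"), "cis")
  expect_error(presume_phase(two_het, evidence = "phased"), "cis")
  # single homozygous variant: phase not applicable
  hom <- make_variant("P2", "CDHR1", "c.783G>A", zygosity = "hom")
  expect_true(is.na(presume_phase(hom)))
  # the same het variant twice is not biallelic
  dup <- rbind(make_variant("P3", "ROM1", "c.339dupG", zygosity = "het"),
               make_variant("P3", "ROM1", "c.339dupG", zygosity = "het"))
  expect_true(is.na(presume_phase(dup)))
})

test_that("verdict rules reproduce the canonical genotype cases", {
  genes <- demo_genes()
  # homozygous recessive frameshift, class 5
  v <- assign_verdict(
    make_variant("P1", "RP1L1", "c.1509del", consequence = "frameshift",
                 gnomad_af = NA, acmg_class = 5L, zygosity = "hom"),
    genes, phenotype = "MD")
  expect_equal(v$status, "very_likely_solved")
  expect_equal(v$causal_gene, "RP1L1")
  expect_equal(v$rationale, "AR_biallelic_class45")

  # heterozygous truncating X-linked variant in a female
  v <- assign_verdict(
    make_variant("P2", "CACNA1F", "c.1566_1575del",
                 consequence = "frameshift", gnomad_af = NA,
                 acmg_class = 4L, zygosity = "het"),
    genes, phenotype = "MD", sex = "F")
  expect_equal(v$status, "possibly_solved")
  expect_equal(v$rationale, "XL_het_truncating_female")

  # heterozygous dominant VUS with deleterious in-silico support
  v <- assign_verdict(
    make_variant("P3", "PRPH2", "c.100C>T", gnomad_af = 1e-05,
                 acmg_class = 3L, zygosity = "het",
                 insilico_deleterious = TRUE),
    genes, phenotype = "MD")
  expect_equal(v$status, "possibly_solved")
  expect_equal(v$rationale, "AD_het_VUS_insilico")

  # an unsupported dominant VUS stays unsolved
  v <- assign_verdict(
    make_variant("P4", "PRPH2", "c.100C>T", gnomad_af = 1e-05,
                 acmg_class = 3L, zygosity = "het"),
    genes)
  expect_equal(v$status, "unsolved")
  expect_true(is.na(v$causal_gene))

  # a single recessive het is a carrier, not a diagnosis
  v <- assign_verdict(
    make_variant("P5", "CDHR1", "c.783G>A", acmg_class = 5L,
                 zygosity = "het"),
    genes)
  expect_equal(v$status, "unsolved")

  # mitochondrial pathogenic variant: solved pending heteroplasmy review
  v <- assign_verdict(
    make_variant("P6", "MT-TL1", "m.3243A>G", gnomad_af = NA,
                 acmg_class = 5L, zygosity = "het"),
    genes)
  expect_equal(v$status, "very_likely_solved")
  expect_equal(v$rationale, "MT_pathogenic_heteroplasmy_review")

  # QC failure dominates everything
  v <- assign_verdict(
    make_variant("P7", "RP1L1", "c.1509del", acmg_class = 5L,
                 zygosity = "hom"),
    genes, qc_pass = FALSE)
  expect_equal(v$status, "failed")
})

test_that("experimental cis phase defuses a presumed compound heterozygote", {
  genes <- demo_genes()
  pair <- rbind(
    make_variant("P1", "PROM1", "c.1A>G", acmg_class = 5L, zygosity = "het"),
    make_variant("P1", "PROM1", "c.2T>C", acmg_class = 5L, zygosity = "het"))
  v <- assign_verdict(pair, genes)
  expect_equal(v$status, "very_likely_solved")
  v <- assign_verdict(pair, genes,
                      phase_evidence = data.frame(gene = "PROM1",
                                                  phase = "cis"))
  expect_equal(v$status, "unsolved")
})

test_that("ABCA4 genotypes route through the severity grammar", {
  genes <- demo_genes()
  sev <- abca4_severity_table(
    hgvs_c = c("c.5882G>A", "c.768G>T", "c.5461-10T>C"),
    sev = c("mild", "severe", "severe"),
    reduced_penetrance = c(TRUE, FALSE, FALSE))
  pair <- rbind(
    make_variant("P1", "ABCA4", "c.5882G>A", gnomad_af = 0.004,
                 acmg_class = 5L, zygosity = "het"),
    make_variant("P1", "ABCA4", "c.768G>T", gnomad_af = NA,
                 acmg_class = 5L, zygosity = "het"))
  # reduced-penetrance mild + severe in a STGD1 proband: possibly solved
  v <- assign_verdict(pair, genes, phenotype = "STGD1",
                      abca4_severities = sev)
  expect_equal(v$status, "possibly_solved")
  expect_equal(v$rationale, "ABCA4_reduced_penetrance_mild_STGD1")
  # same genotype, non-STGD1 phenotype: grammar gives no support
  v <- assign_verdict(pair, genes, phenotype = "CRD",
                      abca4_severities = sev)
  expect_equal(v$status, "unsolved")
  # biallelic severe: very likely solved
  hom <- make_variant("P2", "ABCA4", "c.768G>T", gnomad_af = NA,
                      acmg_class = 5L, zygosity = "hom")
  v <- assign_verdict(hom, genes, phenotype = "STGD1",
                      abca4_severities = sev)
  expect_equal(v$status, "very_likely_solved")
  # uncategorised ABCA4 variants fall back to class-based recessive rules
  plain <- rbind(
    make_variant("P3", "ABCA4", "c.111C>G", gnomad_af = 1e-04,
                 acmg_class = 4L, zygosity = "het"),
    make_variant("P3", "ABCA4", "c.222G>A", gnomad_af = 1e-04,
                 acmg_class = 5L, zygosity = "het"))
  v <- assign_verdict(plain, genes, phenotype = "STGD1")
  expect_equal(v$status, "very_likely_solved")
  expect_equal(v$rationale, "AR_biallelic_class45")
})

test_that("multi-gene probands carry a flag and accept a primary override", {
  genes <- demo_genes()
  vt <- rbind(
    make_variant("P1", "RP1L1", "c.1509del", consequence = "frameshift",
                 gnomad_af = NA, acmg_class = 5L, zygosity = "hom"),
    make_variant("P1", "CDHR1", "c.783G>A", gnomad_af = 0.003052,
                 acmg_class = 5L, zygosity = "hom"))
  v <- assign_verdict(vt, genes)
  expect_true(v$multi_gene)
  expect_setequal(v$candidate_genes, c("RP1L1", "CDHR1"))
  expect_equal(v$causal_gene, "CDHR1")  # alphabetical tie-break
  v <- assign_verdict(vt, genes, primary_gene = "RP1L1")
  expect_equal(v$causal_gene, "RP1L1")
})

test_that("single-gene verdicts agree with the exhaustive rule-table oracle", {
  genes <- demo_genes()
  gene_of <- c(AR = "CDHR1", AD = "PRPH2", XL = "CACNA1F", MT = "MT-TL1")
  for (inh in c("AR", "AD", "XL", "MT")) {
    for (pattern in c("hom", "het1", "het2", "hemi")) {
      if (pattern == "hemi" && inh != "XL") next
      for (cls in 3:5) {
        for (insilico in c(FALSE, TRUE)) {
          for (truncating in c(FALSE, TRUE)) {
            cons <- if (truncating) "frameshift" else "missense"
            g <- gene_of[[inh]]
            vt <- switch(pattern,
              hom = make_variant("PX", g, "c.1A>G", consequence = cons,
                                 acmg_class = cls, zygosity = "hom",
                                 insilico_deleterious = insilico),
              het1 = make_variant("PX", g, "c.1A>G", consequence = cons,
                                  acmg_class = cls, zygosity = "het",
                                  insilico_deleterious = insilico),
              het2 = rbind(
                make_variant("PX", g, "c.1A>G", consequence = cons,
                             acmg_class = cls, zygosity = "het",
                             insilico_deleterious = insilico),
                make_variant("PX", g, "c.2T>C", consequence = cons,
                             acmg_class = cls, zygosity = "het",
                             insilico_deleterious = insilico)),
              hemi = make_variant("PX", g, "c.1A>G", consequence = cons,
                                  acmg_class = cls, zygosity = "hemi",
                                  insilico_deleterious = insilico))
            got <- assign_verdict(vt, genes, sex = "F")$status
            want <- oracle_single_gene_status(inh, pattern, cls, sex = "F",
                                              insilico = insilico,
                                              truncating = truncating)
            expect_equal(got, want,
                         info = sprintf("%s %s class%d isd=%d trunc=%d",
                                        inh, pattern, cls, insilico,
                                        truncating))
          }
        }
      }
    }
  }
})

test_that("every QC-passing proband gets exactly one status (partition)", {
  genes <- demo_genes()
  vt <- suppressWarnings(prioritise(random_variants(400, seed = 3), genes))
  sheet <- data.frame(proband_id = sprintf("P%03d", 1:40),
                      phenotype = "MD", sex = NA_character_,
                      qc_pass = rep(c(TRUE, TRUE, TRUE, FALSE), 10),
                      stringsAsFactors = FALSE)
  verdicts <- assign_verdicts(vt, genes, sheet)
  expect_equal(nrow(verdicts), 40)
  expect_true(all(verdicts$status %in% verdict_levels()))
  tab <- table(factor(verdicts$status, levels = verdict_levels()))
  expect_equal(sum(tab), 40)
  expect_equal(unname(tab["failed"]), 10L)
  # determinism
  expect_identical(verdicts, assign_verdicts(vt, genes, sheet))
})

test_that("cohort summary reproduces the study-shaped fixture arithmetic", {
  genes <- demo_genes()
  # 1352 sequenced: 74 failed, 508 solved (379 AR / 105 AD / 18 XL / 6 MT),
  # 770 unsolved
  gene_for <- c(AR = "CDHR1", AD = "PRPH2", XL = "CACNA1F", MT = "MT-TL1")
  causal <- c(rep(gene_for["AR"], 379), rep(gene_for["AD"], 105),
              rep(gene_for["XL"], 18), rep(gene_for["MT"], 6))
  verdicts <- data.frame(
    proband_id = sprintf("P%04d", 1:1352),
    status = c(rep("very_likely_solved", 508), rep("unsolved", 770),
               rep("failed", 74)),
    causal_gene = c(causal, rep(NA_character_, 770 + 74)),
    multi_gene = FALSE, rationale = "", stringsAsFactors = FALSE)
  s <- cohort_summary(verdicts, genes)
  expect_equal(s$n_sequenced, 1352)
  expect_equal(s$n_failed, 74)
  expect_equal(s$n_solved, 508)
  expect_equal(s$diagnostic_yield, 508 / 1278)
  inh <- s$inheritance_breakdown
  expect_equal(inh$solved_count[inh$inheritance == "AR"], 379L)
  expect_equal(inh$share_pct[inh$inheritance == "AR"], 74.6)
  expect_equal(inh$share_pct[inh$inheritance == "AD"], 20.7)
  expect_equal(inh$share_pct[inh$inheritance == "XL"], 3.5)
  expect_equal(inh$share_pct[inh$inheritance == "MT"], 1.2)
  # shares over solved probands account for everyone
  expect_equal(sum(inh$solved_count), 508L)
})

test_that("gene ranking sorts by count with alphabetical tie-break", {
  genes <- demo_genes()
  causal <- c(rep("ABCA4", 5), rep("PRPH2", 3), rep("CDHR1", 3),
              rep("RP1L1", 2), "PROM1")
  verdicts <- data.frame(
    proband_id = sprintf("P%02d", seq_along(causal)),
    status = "very_likely_solved", causal_gene = causal,
    multi_gene = FALSE, rationale = "", stringsAsFactors = FALSE)
  rank <- cohort_summary(verdicts, genes)$gene_ranking
  counts <- table(causal)
  want <- data.frame(gene = names(counts), solved_count = as.integer(counts),
                     stringsAsFactors = FALSE)
  want <- want[order(-want$solved_count, want$gene), ]
  expect_equal(rank$gene, want$gene)
  expect_equal(rank$solved_count, want$solved_count)
  expect_equal(rank$gene[1:2], c("ABCA4", "CDHR1"))  # tie broken by name
})

test_that("carrier census counts extra mono-allelic class-4/5 alleles only", {
  genes <- demo_genes()
  sev <- abca4_severity_table("c.2588G>C", "mild")
  vt <- rbind(
    # solved proband with an additional het class-5 AR allele: counted
    make_variant("P1", "RP1L1", "c.1509del", acmg_class = 5L,
                 zygosity = "hom"),
    make_variant("P1", "CDHR1", "c.783G>A", acmg_class = 5L,
                 zygosity = "het"),
    # unsolved proband whose only het allele is the excluded ABCA4 variant
    make_variant("P2", "ABCA4", "c.2588G>C", acmg_class = 4L,
                 zygosity = "het"),
    # unsolved proband with a het class-4 AR allele: counted
    make_variant("P3", "PROM1", "c.5T>A", acmg_class = 4L,
                 zygosity = "het"),
    # solved proband whose extra allele is in a dominant gene: not counted
    make_variant("P4", "CDHR1", "c.783G>A", acmg_class = 5L,
                 zygosity = "hom"),
    make_variant("P4", "PRPH2", "c.424C>T", acmg_class = 4L,
                 zygosity = "het"))
  sheet <- data.frame(proband_id = c("P1", "P2", "P3", "P4"),
                      phenotype = "MD", stringsAsFactors = FALSE)
  verdicts <- assign_verdicts(vt, genes, sheet, abca4_severities = sev)
  cc <- carrier_census(verdicts, vt, genes, abca4_severities = sev)
  expect_equal(cc$solved_carriers, 1)
  expect_equal(cc$unsolved_carriers, 1)
  expect_equal(cc$solved_share_pct, 50)
})

test_that("carrier census equals a brute-force re-count on random cohorts", {
  genes <- demo_genes()
  vt <- suppressWarnings(prioritise(random_variants(600, seed = 99), genes))
  sheet <- data.frame(proband_id = sprintf("P%03d", 1:40), phenotype = "MD",
                      stringsAsFactors = FALSE)
  verdicts <- assign_verdicts(vt, genes, sheet)
  cc <- carrier_census(verdicts, vt, genes)
  solved <- verdicts[verdicts$status %in%
                       c("very_likely_solved", "possibly_solved"), ]
  unsolved <- verdicts[verdicts$status == "unsolved", ]
  expect_equal(cc$solved_carriers,
               oracle_carrier_count(solved$proband_id, solved$causal_gene,
                                    vt, genes))
  expect_equal(cc$unsolved_carriers,
               oracle_carrier_count(unsolved$proband_id,
                                    rep(NA_character_, nrow(unsolved)),
                                    vt, genes))
})
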