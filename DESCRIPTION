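Package: macpen
Title: Maculopathy Gene-Panel Interpretation and Penetrance Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Interpretation pipeline for targeted maculopathy gene-panel
    sequencing: inheritance-aware rare-variant prioritisation (allele
    frequency, ACMG class and SpliceAI delta-score gates), an ABCA4
    allele-severity grammar with splice-assay banding, per-proband
    solved-status verdicts and cohort summaries, Hardy-Weinberg based
    penetrance estimation for case-ascertained cohorts, mitochondrial
    heteroplasmy quantification with Lin's concordance validation,
    coverage accounting and sample QC, and a fully synthetic cohort
    generator (Hardy-Weinberg genotypes, genotype-specific penetrance,
    case ascertainment, binomial mtDNA read counts) so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
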