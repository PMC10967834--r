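# Shared fixture builders (everything generated in code)

demo_genes <- function() {
  gene_table(
    gene = c("ABCA4", "PRPH2", "CDHR1", "PROM1", "RP1L1", "CNGB3",
             "CACNA1F", "BEST1", "MT-TL1", "NMNAT1"),
    inheritance = c("AR", "AD", "AR", "AR", "AR", "AR", "XL", "AD", "MT",
                    "AR"))
}

# one fully specified variant row with overridable fields
make_variant <- function(proband_id = "P1", gene = "CDHR1",
                         hgvs_c = "c.783G>A", consequence = "missense",
                         gnomad_af = 0.001, acmg_class = 5L,
                         zygosity = "hom", ...) {
  variant_table(proband_id = proband_id, gene = gene, hgvs_c = hgvs_c,
                consequence = consequence, gnomad_af = gnomad_af,
                acmg_class = acmg_class, zygosity = zygosity, ...)
}

# random annotated variants for property tests
random_variants <- function(n, seed = 1) {
  set.seed(seed)
  genes <- c(demo_genes()$gene, "UNLISTED1")
  cons <- consequence_levels()
  af <- ifelse(runif(n) < 0.15, NA_real_,
               signif(10^runif(n, -6, -1.3), 4))
  cls <- ifelse(runif(n) < 0.15, NA_integer_, sample(1:5, n, replace = TRUE))
  has_ds <- runif(n) < 0.5
  ds <- function() ifelse(has_ds, round(runif(n), 3), NA_real_)
  variant_table(
    proband_id = sprintf("P%03d", sample(40, n, replace = TRUE)),
    gene = sample(genes, n, replace = TRUE),
    hgvs_c = sprintf("c.%dG>A", sample(9000, n, replace = TRUE)),
    consequence = sample(cons, n, replace = TRUE, prob = c(
      0.5, 0.12, 0.12, 0.12, 0.04, 0.03, 0.02, 0.02, 0.02, 0.01)),
    gnomad_af = af, acmg_class = cls,
    zygosity = sample(c("het", "hom", "hemi"), n, replace = TRUE,
                      prob = c(0.7, 0.25, 0.05)),
    ds_ag = ds(), ds_al = ds(), ds_dg = ds(), ds_dl = ds())
}

# plain-text fixture VCF: 2 samples x 3 sites (one multi-annotated, one with
# "." AF, one multi-allelic for the decomposition path when wanted)
write_fixture_vcf <- function(path, samples = c("S1", "S2"),
                              af2 = "0.0005") {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
    "##INFO=<ID=CDNA,Number=1,Type=String,Description=\"HGVS cDNA\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=GAF,Number=1,Type=Float,Description=\"gnomAD AF\">",
    "##INFO=<ID=ACMG,Number=1,Type=Integer,Description=\"ACMG class\">",
    "##INFO=<ID=SPAI,Number=1,Type=String,Description=\"SpliceAI AG|AL|DG|DL\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    paste(c("1", "100", ".", "G", "A", ".", "PASS",
            "GENE=CDHR1;CDNA=c.783G>A;CSQ=splice_altering;GAF=0.003052;ACMG=5;SPAI=0.43|0.21|0|0",
            "GT", "1/1", "0/1"), collapse = "\t"),
    paste(c("1", "200", ".", "C", "T", ".", "PASS",
            sprintf("GENE=PRPH2;CDNA=c.424C>T;CSQ=missense;GAF=%s;ACMG=4", af2),
            "GT", "0/1", "0/0"), collapse = "\t"),
    paste(c("1", "300", ".", "A", "G", ".", "PASS",
            "GENE=RP1L1;CDNA=c.1509del;CSQ=frameshift;GAF=.;ACMG=5",
            "GT", "0/1", "1/1"), collapse = "\t"))
  writeLines(lines, path)
  path
}

write_fixture_gene_tsv <- function(path, extra = NULL) {
  lines <- c("gene\tinheritance", "ABCA4\tAR", "PRPH2\tAD", "CACNA1F\tXL",
             "MT-TL1\tMT", extra)
  writeLines(lines, path)
  path
}
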