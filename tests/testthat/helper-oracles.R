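# Independent oracles, coded from the stated rules without reusing package
# internals. Used by both the module tests and the acceptance suite.

# brute-force gate enumeration for the prioritisation cascade
oracle_filter_keep <- function(df, genes, cfg) {
  inh <- genes$inheritance[match(df$gene, genes$gene)]
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    if (identical(df$consequence[i], "CNV")) { keep[i] <- TRUE; next }
    if (!is.na(df$gene[i]) && df$gene[i] == "ABCA4" &&
        df$hgvs_c[i] %in% cfg$known_abca4) { keep[i] <- TRUE; next }
    if (df$hgvs_c[i] %in% cfg$known_div) { keep[i] <- TRUE; next }
    dominant <- !is.na(inh[i]) && df$zygosity[i] == "het" &&
      (inh[i] == "AD" || (cfg$xl_het_under_ad && inh[i] == "XL"))
    cap <- if (dominant) cfg$af_dominant_het_max else cfg$af_recessive_max
    af_ok <- is.na(df$gnomad_af[i]) || df$gnomad_af[i] <= cap
    acmg_ok <- !is.na(df$acmg_class[i]) &&
      df$acmg_class[i] %in% cfg$acmg_pass_classes
    keep[i] <- af_ok && acmg_ok
  }
  keep
}

# hand-coded severity-pair verdict table (scalar version, independent logic)
oracle_abca4_verdict <- function(a, b, rp_a = FALSE, rp_b = FALSE,
                                 phenotype = NA_character_) {
  lv <- c("no_effect", "mild", "mild_moderately_severe", "moderately_severe",
          "severe")
  ra <- match(a, lv); rb <- match(b, lv)
  if (ra > rb) { tmp <- ra; ra <- rb; rb <- tmp; tmpr <- rp_a; rp_a <- rp_b; rp_b <- tmpr }
  if (ra == 1) return("unsolved")                       # no_effect allele
  if (ra == 2 && rb == 2) return("unsolved")            # mild + mild
  if (ra == 2) {                                        # mild + stronger
    if (rp_a) {
      if (rb >= 3 && identical(phenotype, "STGD1")) return("possibly_solved")
      return("unsolved")
    }
    if (rb == 5) return("very_likely_solved")
    return("possibly_solved")
  }
  if (ra == 3 && rb == 3) return("possibly_solved")     # mild-mod twice
  "very_likely_solved"
}

# independent status lookup for single-gene, class-based genotypes
oracle_single_gene_status <- function(inheritance, pattern, cls, sex = "F",
                                      insilico = FALSE,
                                      truncating = FALSE) {
  # pattern: "hom", "het1" (one het), "het2" (two distinct het, presumed
  # trans), "hemi"
  if (inheritance == "MT") {
    return(if (cls >= 4) "very_likely_solved" else "unsolved")
  }
  if (inheritance == "AD") {
    if (pattern %in% c("hom", "het1", "het2") && cls >= 4)
      return("very_likely_solved")
    if (pattern %in% c("het1", "het2") && cls == 3 && insilico)
      return("possibly_solved")
    return("unsolved")
  }
  if (inheritance == "XL") {
    if (pattern == "hemi" && cls >= 4) return("very_likely_solved")
    if (pattern == "hom" && cls >= 4) return("very_likely_solved")
    if (pattern %in% c("het1", "het2") && cls >= 4 && truncating &&
        sex %in% c("F", NA)) return("possibly_solved")
    return("unsolved")
  }
  # AR
  if (pattern == "hom" && cls >= 4) return("very_likely_solved")
  if (pattern == "hom" && cls == 3) return("possibly_solved")
  if (pattern == "het2" && cls >= 4) return("very_likely_solved")
  if (pattern == "het2" && cls == 3) return("possibly_solved")
  "unsolved"
}

# direct textbook formula for Lin's concordance (population moments)
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# brute-force carrier re-count mirroring the census definition
oracle_carrier_count <- function(ids, causal, variants, genes,
                                 abca4_sev = NULL, exclude = "c.2588G>C") {
  hits <- 0L
  for (i in seq_along(ids)) {
    pv <- variants[variants$proband_id == ids[i], , drop = FALSE]
    pv <- pv[!pv$hgvs_c %in% exclude, , drop = FALSE]
    if (!is.na(causal[i])) pv <- pv[pv$gene != causal[i], , drop = FALSE]
    found <- FALSE
    for (g in unique(pv$gene)) {
      gv <- pv[pv$gene == g, , drop = FALSE]
      if (nrow(gv) != 1 || gv$zygosity != "het") next
      inh <- genes$inheritance[genes$gene == g]
      cls45 <- !is.na(gv$acmg_class) && gv$acmg_class >= 4
      sev <- gv$abca4_severity
      if (is.na(sev) && !is.null(abca4_sev)) {
        m <- match(gv$hgvs_c, abca4_sev$hgvs_c)
        if (!is.na(m)) sev <- abca4_sev$severity[m]
      }
      cat_ok <- g == "ABCA4" && !is.na(sev) && sev != "no_effect"
      if ((cls45 && length(inh) == 1 && inh == "AR") || cat_ok) {
        found <- TRUE
        break
      }
    }
    if (found) hits <- hits + 1L
  }
  hits
}
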