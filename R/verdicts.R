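# Per-proband solved-status verdicts and cohort summaries --------------------

#' Presume the phase of multiple variants in one gene
#'
#' With no segregation or long-read evidence, two or more distinct rare
#' heterozygous variants in a single gene are presumed to sit on opposite
#' haplotypes (compound heterozygous). Experimental phase evidence, when
#' supplied, overrides the presumption.
#'
#' @param gene_variants variant-table rows of one proband in one gene
#' @param evidence optional experimentally determined phase (`"cis"` or
#'   `"trans"`)
#' @return `"cis"`, `"trans"`, `"presumed_trans"` or `NA` (phase not
#'   applicable: fewer than two distinct heterozygous variants)
#' @export
presume_phase <- function(gene_variants, evidence = NA_character_) {
  if (!is.na(evidence)) {
    if (!evidence %in% c("cis", "trans")) {
      stop("phase evidence must be \"cis\" or \"trans\"", call. = FALSE)
    }
    return(evidence)
  }
  het <- gene_variants[gene_variants$zygosity == "het", , drop = FALSE]
  if (length(unique(het$hgvs_c)) >= 2) "presumed_trans" else NA_character_
}

sev_rank <- function(s) match(s, severity_levels())

resolve_abca4_severity <- function(gv, abca4_severities) {
  sev <- gv$abca4_severity
  rp <- rep(FALSE, nrow(gv))
  if (!is.null(abca4_severities)) {
    idx <- match(gv$hgvs_c, abca4_severities$hgvs_c)
    sev <- ifelse(is.na(sev) & !is.na(idx), abca4_severities$severity[idx], sev)
    rp <- !is.na(idx) & abca4_severities$reduced_penetrance[idx] %in% TRUE
  }
  list(severity = sev, reduced_penetrance = rp)
}

# evaluate one proband x gene; returns candidate verdict contribution
eval_gene_genotype <- function(gv, inheritance, phenotype, sex,
                               abca4_severities, phase) {
  none <- list(status = "unsolved", rule = NA_character_, class45 = FALSE)
  cls <- gv$acmg_class
  is45 <- !is.na(cls) & cls >= 4
  is_vus <- !is.na(cls) & cls == 3
  hom <- gv$zygosity == "hom"
  het <- gv$zygosity == "het"
  hemi <- gv$zygosity == "hemi"
  inh <- if (is.na(inheritance)) "AR" else inheritance

  if (inh == "MT") {
    if (any(is45)) {
      return(list(status = "very_likely_solved",
                  rule = "MT_pathogenic_heteroplasmy_review", class45 = TRUE))
    }
    return(none)
  }

  # ABCA4 severity grammar, when every variant in the gene is categorised
  if (identical(unique(gv$gene), "ABCA4")) {
    res <- resolve_abca4_severity(gv, abca4_severities)
    if (!anyNA(res$severity) && nrow(gv) > 0) {
      if (any(hom)) {
        i <- which(hom)[which.max(sev_rank(res$severity[hom]))]
        v <- abca4_genotype_verdict(res$severity[i], res$severity[i],
                                    phenotype,
                                    rep(res$reduced_penetrance[i], 2),
                                    phase = "presumed_trans")
        return(list(status = v$status, rule = v$rule,
                    class45 = v$status == "very_likely_solved"))
      }
      distinct <- !duplicated(gv$hgvs_c)
      hd <- which(het & distinct)
      if (length(hd) >= 2 && phase %in% c("trans", "presumed_trans")) {
        top <- hd[order(-sev_rank(res$severity[hd]))][1:2]
        v <- abca4_genotype_verdict(res$severity[top[1]], res$severity[top[2]],
                                    phenotype,
                                    res$reduced_penetrance[top],
                                    phase = phase)
        return(list(status = v$status, rule = v$rule,
                    class45 = v$status == "very_likely_solved"))
      }
      return(none)  # mono-allelic, or experimentally in cis
    }
    # fall through to class-based recessive rules when uncategorised
  }

  if (inh == "AD") {
    if (any((het | hom) & is45)) {
      return(list(status = "very_likely_solved", rule = "AD_het_class45",
                  class45 = TRUE))
    }
    if (any(het & is_vus & gv$insilico_deleterious %in% TRUE)) {
      return(list(status = "possibly_solved", rule = "AD_het_VUS_insilico",
                  class45 = FALSE))
    }
    return(none)
  }

  if (inh == "XL") {
    if (any(hemi & is45)) {
      return(list(status = "very_likely_solved", rule = "XL_hemi_class45",
                  class45 = TRUE))
    }
    if (any(hom & is45)) {
      return(list(status = "very_likely_solved", rule = "XL_biallelic_class45",
                  class45 = TRUE))
    }
    truncating <- gv$consequence %in% c("frameshift", "nonsense", "start_lost")
    female <- is.na(sex) || sex == "F"
    if (female && any(het & is45 & truncating)) {
      return(list(status = "possibly_solved",
                  rule = "XL_het_truncating_female", class45 = FALSE))
    }
    return(none)
  }

  # AR (and unknown inheritance, evaluated as biallelic-only)
  if (any(hom & is45)) {
    return(list(status = "very_likely_solved", rule = "AR_biallelic_class45",
                class45 = TRUE))
  }
  distinct <- !duplicated(gv$hgvs_c)
  n_het45 <- length(unique(gv$hgvs_c[het & is45 & distinct]))
  n_het_345 <- length(unique(gv$hgvs_c[het & (is45 | is_vus) & distinct]))
  if (phase %in% c("trans", "presumed_trans")) {
    if (n_het45 >= 2) {
      return(list(status = "very_likely_solved",
                  rule = "AR_biallelic_class45", class45 = TRUE))
    }
    if (n_het_345 >= 2 && any(het & is_vus)) {
      return(list(status = "possibly_solved", rule = "AR_biallelic_with_VUS",
                  class45 = FALSE))
    }
  }
  if (any(hom & is_vus)) {
    return(list(status = "possibly_solved", rule = "AR_biallelic_with_VUS",
                class45 = FALSE))
  }
  none
}

#' Assign a solved-status verdict to one proband
#'
#' Applies the rule set gene by gene on the prioritised genotype and keeps
#' the strongest contribution (very likely > possibly > unsolved):
#' biallelic class-4/5 genotypes in recessive genes, the ABCA4 severity
#' grammar, heterozygous class-4/5 (or supported VUS) in dominant genes,
#' hemizygous class-4/5 in X-linked genes (heterozygous truncating variants
#' in females give a possible verdict), and pathogenic mitochondrial
#' variants (flagged for heteroplasmy review). When class-4/5 genotypes
#' exist in more than one gene all genes are reported, the verdict carries
#' a multi-gene flag, and an externally supplied primary gene (clinical
#' adjudication) selects the causal gene.
#'
#' @param proband_variants prioritised variant rows of a single proband
#' @param genes gene table
#' @param phenotype,sex proband phenotype label and sex (`"F"`/`"M"`/`NA`)
#' @param qc_pass did the sample pass sequencing QC?
#' @param abca4_severities optional [abca4_severity_table()]
#' @param phase_evidence optional data.frame (`gene`, `phase`) of
#'   experimentally phased genes for this proband
#' @param primary_gene optional externally adjudicated causal gene
#' @return list of class `macpen_verdict`: `status`, `causal_gene`,
#'   `rationale` (rule identifiers), `multi_gene`, `candidate_genes`
#' @export
assign_verdict <- function(proband_variants, genes,
                           phenotype = NA_character_, sex = NA_character_,
                           qc_pass = TRUE, abca4_severities = NULL,
                           phase_evidence = NULL,
                           primary_gene = NA_character_) {
  if (!isTRUE(qc_pass)) {
    return(structure(list(status = "failed", causal_gene = NA_character_,
                          rationale = "QC_failed", multi_gene = FALSE,
                          candidate_genes = character()),
                     class = "macpen_verdict"))
  }
  gv_split <- split(as.data.frame(proband_variants),
                    proband_variants$gene)
  cands <- list()
  for (g in sort(names(gv_split))) {
    gv <- gv_split[[g]]
    ev <- NA_character_
    if (!is.null(phase_evidence)) {
      hit <- phase_evidence$phase[phase_evidence$gene == g]
      if (length(hit) == 1) ev <- hit
    }
    phase <- presume_phase(gv, ev)
    inh <- genes$inheritance[match(g, genes$gene)]
    res <- eval_gene_genotype(gv, inh, phenotype, sex, abca4_severities,
                              phase)
    if (res$status != "unsolved" || isTRUE(res$class45)) {
      cands[[g]] <- res
    }
  }
  solved <- Filter(function(x) x$status != "unsolved", cands)
  if (length(solved) == 0) {
    return(structure(list(status = "unsolved", causal_gene = NA_character_,
                          rationale = "no_qualifying_genotype",
                          multi_gene = FALSE, candidate_genes = character()),
                     class = "macpen_verdict"))
  }
  rank <- vapply(solved, function(x)
    match(x$status, c("very_likely_solved", "possibly_solved")), 1L)
  best_rank <- min(rank)
  top_genes <- sort(names(solved)[rank == best_rank])
  n_class45_genes <- sum(vapply(cands, function(x) isTRUE(x$class45), TRUE))
  multi <- n_class45_genes > 1
  causal <- top_genes[1]
  if (!is.na(primary_gene) && primary_gene %in% names(solved)) {
    causal <- primary_gene
  }
  rules <- vapply(solved, `[[`, "", "rule")
  structure(list(status = solved[[causal]]$status, causal_gene = causal,
                 rationale = unname(rules[order(names(solved))]),
                 multi_gene = multi,
                 candidate_genes = sort(names(solved))),
            class = "macpen_verdict")
}

#' Assign verdicts across a cohort
#'
#' @param variants prioritised variant table (all probands)
#' @param genes gene table
#' @param sample_sheet data.frame with `proband_id` and optional
#'   `phenotype`, `sex`, `qc_pass` columns; every listed proband receives a
#'   verdict even with no retained variants
#' @param abca4_severities optional [abca4_severity_table()]
#' @param phase_evidence optional data.frame (`proband_id`, `gene`, `phase`)
#' @param primary_overrides optional data.frame (`proband_id`, `gene`) of
#'   clinically adjudicated primary genes for multi-gene probands
#' @return data.frame: `proband_id`, `status`, `causal_gene`, `multi_gene`,
#'   `rationale` (comma-separated rule ids), `candidate_genes`
#' @export
assign_verdicts <- function(variants, genes, sample_sheet,
                            abca4_severities = NULL, phase_evidence = NULL,
                            primary_overrides = NULL) {
  out <- vector("list", nrow(sample_sheet))
  for (i in seq_len(nrow(sample_sheet))) {
    id <- sample_sheet$proband_id[i]
    pv <- variants[variants$proband_id == id, , drop = FALSE]
    pe <- if (is.null(phase_evidence)) NULL else
      phase_evidence[phase_evidence$proband_id == id, , drop = FALSE]
    po <- NA_character_
    if (!is.null(primary_overrides)) {
      hit <- primary_overrides$gene[primary_overrides$proband_id == id]
      if (length(hit) == 1) po <- hit
    }
    v <- assign_verdict(
      pv, genes,
      phenotype = sample_sheet$phenotype[i] %||% NA_character_,
      sex = if ("sex" %in% names(sample_sheet)) sample_sheet$sex[i] else NA_character_,
      qc_pass = if ("qc_pass" %in% names(sample_sheet)) sample_sheet$qc_pass[i] else TRUE,
      abca4_severities = abca4_severities, phase_evidence = pe,
      primary_gene = po)
    out[[i]] <- data.frame(
      proband_id = id, status = v$status, causal_gene = v$causal_gene,
      multi_gene = v$multi_gene,
      rationale = paste(v$rationale, collapse = ","),
      candidate_genes = paste(v$candidate_genes, collapse = ","),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

solved_statuses <- function() c("very_likely_solved", "possibly_solved")

#' Cohort summary statistics
#'
#' Diagnostic yield (solved / QC-passing), causative-gene ranking
#' (count-descending, alphabetical tie-break), inheritance-mode breakdown
#' over solved probands and the multi-gene proband count. Shares are
#' percentages rounded half-up to one decimal.
#'
#' @param verdicts data.frame from [assign_verdicts()]
#' @param genes gene table
#' @return list of class `macpen_cohort_summary`
#' @export
cohort_summary <- function(verdicts, genes) {
  n_sequenced <- nrow(verdicts)
  n_failed <- sum(verdicts$status == "failed")
  solved <- verdicts[verdicts$status %in% solved_statuses(), , drop = FALSE]
  n_solved <- nrow(solved)
  denom <- n_sequenced - n_failed
  yield <- if (denom > 0) n_solved / denom else NA_real_

  counts <- table(solved$causal_gene)
  rank <- data.frame(gene = names(counts), solved_count = as.integer(counts),
                     stringsAsFactors = FALSE)
  rank <- rank[order(-rank$solved_count, rank$gene), , drop = FALSE]
  rank$share_pct <- as_percent(rank$solved_count / max(n_solved, 1))
  rownames(rank) <- NULL

  inh <- genes$inheritance[match(solved$causal_gene, genes$gene)]
  inh_counts <- vapply(inheritance_levels(),
                       function(m) sum(inh %in% m), 1L)
  inh_break <- data.frame(inheritance = inheritance_levels(),
                          solved_count = inh_counts,
                          share_pct = as_percent(inh_counts / max(n_solved, 1)),
                          stringsAsFactors = FALSE)

  structure(list(n_sequenced = n_sequenced, n_failed = n_failed,
                 n_solved = n_solved,
                 diagnostic_yield = yield,
                 diagnostic_yield_pct = as_percent(yield),
                 gene_ranking = rank, inheritance_breakdown = inh_break,
                 multi_gene_probands = sum(verdicts$multi_gene %in% TRUE)),
            class = "macpen_cohort_summary")
}

#' @exportS3Method base::print
print.macpen_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d sequenced, %d failed QC, %d solved (yield %.1f%%)\n",
              x$n_sequenced, x$n_failed, x$n_solved, x$diagnostic_yield_pct))
  cat("Top causative genes:\n")
  print(utils::head(x$gene_ranking, 5), row.names = FALSE)
  cat("Inheritance breakdown (solved probands):\n")
  print(x$inheritance_breakdown, row.names = FALSE)
  invisible(x)
}

#' Census of mono-allelic (likely) pathogenic carriers
#'
#' Counts probands, separately in the solved and unsolved cohorts, that
#' carry at least one additional mono-allelic class-4/5 variant in a
#' recessive gene, or a severity-categorised ABCA4 allele. A configured
#' exclusion list (default ABCA4 c.2588G>C, benign when not in cis with
#' c.5603A>T) is skipped; for solved probands the causal gene itself is not
#' counted.
#'
#' @param verdicts data.frame from [assign_verdicts()]
#' @param variants prioritised variant table
#' @param genes gene table
#' @param abca4_severities optional [abca4_severity_table()]
#' @param exclude HGVS strings never counted (default `"c.2588G>C"`)
#' @return list: counts and shares for the solved and unsolved cohorts
#' @export
carrier_census <- function(verdicts, variants, genes,
                           abca4_severities = NULL,
                           exclude = "c.2588G>C") {
  is_carrier <- function(id, causal_gene) {
    pv <- variants[variants$proband_id == id, , drop = FALSE]
    if (nrow(pv) == 0) return(FALSE)
    pv <- pv[!(pv$hgvs_c %in% exclude), , drop = FALSE]
    if (!is.na(causal_gene)) pv <- pv[pv$gene != causal_gene, , drop = FALSE]
    if (nrow(pv) == 0) return(FALSE)
    n_in_gene <- table(pv$gene)
    mono <- pv$zygosity == "het" & n_in_gene[pv$gene] == 1
    inh <- genes$inheritance[match(pv$gene, genes$gene)]
    cls45 <- !is.na(pv$acmg_class) & pv$acmg_class >= 4
    sev <- resolve_abca4_severity(pv, abca4_severities)$severity
    categorised <- pv$gene == "ABCA4" & !is.na(sev) & sev != "no_effect"
    any(mono & ((cls45 & inh %in% "AR") | categorised))
  }
  solved <- verdicts[verdicts$status %in% solved_statuses(), , drop = FALSE]
  unsolved <- verdicts[verdicts$status == "unsolved", , drop = FALSE]
  n_solved_carriers <- sum(mapply(is_carrier, solved$proband_id,
                                  solved$causal_gene))
  n_unsolved_carriers <- sum(vapply(unsolved$proband_id,
                                    function(id) is_carrier(id, NA_character_),
                                    TRUE))
  list(solved_carriers = n_solved_carriers,
       solved_share_pct = as_percent(n_solved_carriers / max(nrow(solved), 1)),
       unsolved_carriers = n_unsolved_carriers,
       unsolved_share_pct = as_percent(n_unsolved_carriers /
                                         max(nrow(unsolved), 1)))
}
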