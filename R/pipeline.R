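# End-to-end pipeline ---------------------------------------------------------

#' Run the full interpretation pipeline on a cohort
#'
#' Composes the stages in order: sample QC, variant prioritisation, verdict
#' assignment, cohort summary, reduced-penetrance census, penetrance
#' estimation for requested genotypes, and mtDNA target extraction. Writes a
#' results bundle (verdicts, penetrance table, rationale JSON, summary JSON
#' and a manifest of the configuration) whose bytes are identical on rerun
#' with the same inputs.
#'
#' @param variants cohort variant table (e.g. from [read_annotated_vcf()] or
#'   [simulate_cohort()])
#' @param genes gene table
#' @param sample_sheet data.frame with `proband_id` and optional
#'   `phenotype`, `sex` columns
#' @param read_stats optional data.frame for [sample_qc()]; probands absent
#'   from it are assumed to pass
#' @param cfg [filter_config()]
#' @param abca4_severities optional [abca4_severity_table()]
#' @param phase_evidence,primary_overrides optional, see [assign_verdicts()]
#' @param penetrance_specs optional list of lists with fields `spec`
#'   ([genotype_spec()]) and `observed_count`; `cohort_n` defaults to the
#'   sample-sheet size
#' @param prevalence assumed disease prevalence for penetrance estimation
#' @param mtdna_pileup optional pileup data.frame for
#'   [extract_target_variant()]
#' @param out_dir optional output directory for the results bundle
#' @param min_avg_coverage QC floor passed to [sample_qc()]
#' @return list of class `macpen_results`: `verdicts`, `summary`,
#'   `carriers`, `reduced_penetrance`, `penetrance`, `mtdna_calls`,
#'   `prioritised`
#' @export
run_pipeline <- function(variants, genes, sample_sheet, read_stats = NULL,
                         cfg = filter_config(), abca4_severities = NULL,
                         phase_evidence = NULL, primary_overrides = NULL,
                         penetrance_specs = NULL, prevalence = 1 / 5000,
                         mtdna_pileup = NULL, out_dir = NULL,
                         min_avg_coverage = 10) {
  sheet <- sample_sheet
  if (!"qc_pass" %in% names(sheet)) sheet$qc_pass <- TRUE
  if (!is.null(read_stats)) {
    qc <- sample_qc(read_stats, min_avg_coverage)
    idx <- match(sheet$proband_id, qc$sample_id)
    sheet$qc_pass <- ifelse(is.na(idx), sheet$qc_pass, qc$qc_pass[idx])
  }
  prioritised <- prioritise(variants, genes, cfg)
  verdicts <- assign_verdicts(prioritised, genes, sheet,
                              abca4_severities = abca4_severities,
                              phase_evidence = phase_evidence,
                              primary_overrides = primary_overrides)
  summary <- cohort_summary(verdicts, genes)
  carriers <- carrier_census(verdicts, prioritised, genes, abca4_severities)
  rp_census <- reduced_penetrance_census(verdicts, prioritised)

  pen_table <- NULL
  if (!is.null(penetrance_specs)) {
    rows <- lapply(penetrance_specs, function(ps) {
      n <- ps$cohort_n %||% nrow(sheet)
      est <- estimate_penetrance(ps$observed_count, n, prevalence,
                                 hw_genotype_frequency(ps$spec),
                                 spec = ps$spec)
      data.frame(genotype = paste(ps$spec$labels %||% ps$spec$kind,
                                  collapse = "/"),
                 observed_count = est$observed_count, cohort_n = est$cohort_n,
                 p_x_given_d = est$p_x_given_d, prevalence = est$prevalence,
                 p_x = est$p_x, penetrance = est$penetrance, flag = est$flag,
                 stringsAsFactors = FALSE)
    })
    pen_table <- do.call(rbind, rows)
  }

  mt_calls <- if (is.null(mtdna_pileup)) list() else
    extract_target_variant(mtdna_pileup)

  res <- structure(list(verdicts = verdicts, summary = summary,
                        carriers = carriers, reduced_penetrance = rp_census,
                        penetrance = pen_table, mtdna_calls = mt_calls,
                        prioritised = prioritised),
                   class = "macpen_results")

  if (!is.null(out_dir)) {
    write_results(verdicts, pen_table, out_dir)
    jsonlite::write_json(
      list(n_sequenced = summary$n_sequenced, n_failed = summary$n_failed,
           n_solved = summary$n_solved,
           diagnostic_yield_pct = summary$diagnostic_yield_pct,
           gene_ranking = summary$gene_ranking,
           inheritance_breakdown = summary$inheritance_breakdown,
           multi_gene_probands = summary$multi_gene_probands,
           carriers = carriers,
           reduced_penetrance = rp_census),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    manifest <- list(
      n_probands = nrow(sheet), prevalence = prevalence,
      filter = unclass(cfg), min_avg_coverage = min_avg_coverage)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (length(mt_calls) > 0) {
      mt <- do.call(rbind, lapply(mt_calls, function(x)
        data.frame(sample = x$sample, position = x$position,
                   ref_count = x$ref_count, alt_count = x$alt_count,
                   fraction = x$fraction, reliable = x$reliable,
                   caller_detected = x$caller_detected,
                   stringsAsFactors = FALSE)))
      utils::write.table(mt, file.path(out_dir, "mtdna.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  res
}
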