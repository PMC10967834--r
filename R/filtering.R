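# Prioritisation cascade: allele-frequency, ACMG-class and splice-score gates

#' Filter configuration
#'
#' Thresholds of the prioritisation cascade. Defaults: biallelic candidates
#' (homozygous or potentially compound-heterozygous) are kept at minor
#' AF <= 0.5%; heterozygous variants in dominant-disease genes at
#' AF <= 0.1%; SpliceAI candidates need a delta score >= 0.2 in at least one
#' of the four channels; only ACMG classes 3-5 (VUS, likely pathogenic,
#' pathogenic) pass the class gate.
#'
#' @param af_recessive_max AF ceiling for hom/biallelic candidates
#' @param af_dominant_het_max AF ceiling for heterozygous variants in AD genes
#' @param ds_min minimum SpliceAI delta score for splice-candidate flagging
#' @param acmg_pass_classes integer vector of passing ACMG classes
#' @param xl_het_under_ad should heterozygous variants in X-linked genes
#'   (female carriers) be held to the dominant threshold? Hemizygous calls
#'   always use the recessive threshold.
#' @param known_abca4 character vector of HGVS cDNA strings: published ABCA4
#'   variants extracted with highest priority regardless of the gates
#' @param known_div character vector of HGVS cDNA strings: known pathogenic
#'   deep-intronic variants, extracted regardless of consequence
#' @return list of class `macpen_filter_config`
#' @export
filter_config <- function(af_recessive_max = 0.005,
                          af_dominant_het_max = 0.001,
                          ds_min = 0.2,
                          acmg_pass_classes = c(3L, 4L, 5L),
                          xl_het_under_ad = TRUE,
                          known_abca4 = character(),
                          known_div = character()) {
  stop_if_not_scalar_number(af_recessive_max, "af_recessive_max", 0, 1)
  stop_if_not_scalar_number(af_dominant_het_max, "af_dominant_het_max", 0, 1)
  stop_if_not_scalar_number(ds_min, "ds_min", 0, 1)
  stopifnot(all(acmg_pass_classes %in% 1:5))
  structure(list(af_recessive_max = af_recessive_max,
                 af_dominant_het_max = af_dominant_het_max,
                 ds_min = ds_min,
                 acmg_pass_classes = as.integer(acmg_pass_classes),
                 xl_het_under_ad = isTRUE(xl_het_under_ad),
                 known_abca4 = as.character(known_abca4),
                 known_div = as.character(known_div)),
            class = "macpen_filter_config")
}

#' Allele-frequency gate
#'
#' Homozygous/hemizygous calls and heterozygous candidates in recessive
#' context pass iff AF <= `af_recessive_max`; heterozygous variants in
#' dominant-disease genes iff AF <= `af_dominant_het_max`. An unknown AF
#' (absent from the population database) is treated as rare and passes.
#'
#' @param gnomad_af population AF vector (`NA` = unknown)
#' @param zygosity `"het"`, `"hom"` or `"hemi"` (recycled)
#' @param inheritance inheritance mode of the gene (`NA` = gene not on the
#'   panel table: evaluated under the recessive threshold)
#' @param cfg [filter_config()]
#' @return logical vector
#' @export
passes_af_filter <- function(gnomad_af, zygosity, inheritance,
                             cfg = filter_config()) {
  n <- max(length(gnomad_af), length(zygosity), length(inheritance))
  af <- rep_len(gnomad_af, n)
  zyg <- rep_len(as.character(zygosity), n)
  inh <- rep_len(as.character(inheritance), n)
  dominant_context <- zyg == "het" &
    (inh %in% "AD" | (cfg$xl_het_under_ad & inh %in% "XL"))
  threshold <- ifelse(dominant_context, cfg$af_dominant_het_max,
                      cfg$af_recessive_max)
  is.na(af) | af <= threshold
}

#' ACMG class gate
#'
#' Passes iff the class is in `acmg_pass_classes`; an unknown class fails
#' (only classified variants were prioritised).
#'
#' @param acmg_class integer vector (`NA` = unknown)
#' @param cfg [filter_config()]
#' @return logical vector
#' @export
passes_acmg_filter <- function(acmg_class, cfg = filter_config()) {
  !is.na(acmg_class) & acmg_class %in% cfg$acmg_pass_classes
}

#' SpliceAI candidate gate
#'
#' A variant is a splice candidate when at least one of the four delta
#' scores (acceptor/donor gain/loss) reaches `ds_min`.
#'
#' @param ag,al,dg,dl delta scores in \[0, 1\]; all four must be present
#' @param cfg [filter_config()]
#' @return logical vector
#' @export
is_splice_candidate <- function(ag, al, dg, dl, cfg = filter_config()) {
  scores <- cbind(ag, al, dg, dl)
  if (anyNA(scores)) {
    stop("all four delta scores must be present", call. = FALSE)
  }
  if (any(scores < 0 | scores > 1)) {
    stop("delta scores must lie in [0, 1]", call. = FALSE)
  }
  apply(scores, 1, max) >= cfg$ds_min
}

# splice flag for the cascade: missing scores simply mean "not flagged"
splice_flag <- function(df, cfg) {
  scores <- as.matrix(df[, c("ds_ag", "ds_al", "ds_dg", "ds_dl")])
  flag <- suppressWarnings(apply(scores, 1, max, na.rm = TRUE)) >= cfg$ds_min
  flag[!is.finite(suppressWarnings(apply(scores, 1, max, na.rm = TRUE)))] <- FALSE
  flag & !apply(is.na(scores), 1, all)
}

#' Prioritise a cohort's variants through the selection cascade
#'
#' Ordered cascade: (1) CNV records pass through unfiltered, flagged
#' `cnv_external` (CNV calling is delegated upstream); (2) published ABCA4
#' variants in `cfg$known_abca4` are extracted with highest priority; (3)
#' known deep-intronic variants in `cfg$known_div` are extracted regardless
#' of consequence; (4) remaining SNVs/indels are kept iff they pass both the
#' AF and ACMG gates. Splice candidates are flagged, never used to rescue or
#' drop a variant. The output is always a subset of the input rows, plus
#' flag columns, and the cascade is idempotent.
#'
#' Genes absent from the gene table trigger a warning; their variants are
#' evaluated with unknown inheritance (recessive AF threshold, so they can
#' only contribute as biallelic candidates downstream).
#'
#' @param variants `macpen_variants` table (any number of probands)
#' @param genes gene table from [read_gene_table()]
#' @param cfg [filter_config()]
#' @return filtered variant table with added columns `inheritance`,
#'   `flag_cnv_external`, `flag_known_abca4`, `flag_known_div`,
#'   `flag_splice_candidate`
#' @export
prioritise <- function(variants, genes, cfg = filter_config()) {
  df <- as.data.frame(variants)
  df$inheritance <- genes$inheritance[match(df$gene, genes$gene)]
  unknown_genes <- setdiff(unique(df$gene[!is.na(df$gene)]), genes$gene)
  if (length(unknown_genes) > 0) {
    warning("gene(s) not in gene table, inheritance unknown: ",
            paste(unknown_genes, collapse = ", "), call. = FALSE)
  }
  df$flag_cnv_external <- !is.na(df$consequence) & df$consequence == "CNV"
  df$flag_known_abca4 <- !is.na(df$gene) & df$gene == "ABCA4" &
    df$hgvs_c %in% cfg$known_abca4
  df$flag_known_div <- df$hgvs_c %in% cfg$known_div
  df$flag_splice_candidate <- splice_flag(df, cfg)
  gate <- passes_af_filter(df$gnomad_af, df$zygosity, df$inheritance, cfg) &
    passes_acmg_filter(df$acmg_class, cfg)
  keep <- df$flag_cnv_external | df$flag_known_abca4 | df$flag_known_div | gate
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("macpen_variants", class(out)))
  out
}
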