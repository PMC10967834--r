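# Domain vocabularies -------------------------------------------------------

#' Closed vocabulary of variant consequences
#'
#' The ten consequence categories used throughout the pipeline: missense,
#' frameshift, nonsense, splice-altering, CNV, in-frame deletion, in-frame
#' insertion, start-lost, downstream and 5'UTR.
#'
#' @return character vector of consequence labels
#' @export
consequence_levels <- function() {
  c("missense", "frameshift", "nonsense", "splice_altering", "CNV",
    "inframe_deletion", "inframe_insertion", "start_lost", "downstream",
    "utr5")
}

#' Inheritance modes recognised by the gene table
#' @return character vector: autosomal recessive, autosomal dominant,
#'   X-linked, mitochondrial
#' @export
inheritance_levels <- function() c("AR", "AD", "XL", "MT")

#' Verdict statuses
#' @return character vector of the four solved-status levels
#' @export
verdict_levels <- function() {
  c("very_likely_solved", "possibly_solved", "unsolved", "failed")
}

#' ABCA4 allele severity scale
#'
#' Ordered severity categories based on residual ABCA4 protein activity,
#' from no functional effect to severe (null-like).
#'
#' @return character vector of severity levels in increasing order
#' @export
severity_levels <- function() {
  c("no_effect", "mild", "mild_moderately_severe", "moderately_severe",
    "severe")
}

#' Construct an ordered severity factor
#'
#' @param x character vector of severity labels (see [severity_levels()])
#' @return ordered factor on the severity scale
#' @export
severity <- function(x) {
  lv <- severity_levels()
  bad <- setdiff(unique(as.character(x[!is.na(x)])), lv)
  if (length(bad) > 0) {
    stop("unknown severity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(as.character(x), levels = lv, ordered = TRUE)
}

# Variant table --------------------------------------------------------------

variant_table_columns <- function() {
  c("proband_id", "gene", "hgvs_c", "chrom", "pos", "ref", "alt",
    "consequence", "gnomad_af", "acmg_class", "zygosity",
    "ds_ag", "ds_al", "ds_dg", "ds_dl", "abca4_severity",
    "insilico_deleterious")
}

#' Build a validated variant table
#'
#' The central container: one row per proband x variant allele, with the
#' annotations the prioritisation cascade consumes. Missing annotations are
#' `NA` (unknown), never a silent numeric default.
#'
#' @param proband_id,gene,hgvs_c,chrom,ref,alt character vectors
#' @param pos 1-based integer positions
#' @param consequence one of [consequence_levels()]
#' @param gnomad_af population allele frequency in \[0, 1\], `NA` = absent
#'   from the population database
#' @param acmg_class integer 1-5, `NA` = unclassified
#' @param zygosity one of `"het"`, `"hom"`, `"hemi"`
#' @param ds_ag,ds_al,ds_dg,ds_dl SpliceAI delta scores in \[0, 1\] (optional)
#' @param abca4_severity severity label for ABCA4 alleles (optional)
#' @param insilico_deleterious logical: deleterious in-silico support
#'   (optional, used for dominant VUS adjudication)
#' @return data.frame of class `macpen_variants`
#' @export
variant_table <- function(proband_id, gene, hgvs_c, chrom = NA_character_,
                          pos = NA_integer_, ref = NA_character_,
                          alt = NA_character_, consequence = "missense",
                          gnomad_af = NA_real_, acmg_class = NA_integer_,
                          zygosity = "het", ds_ag = NA_real_,
                          ds_al = NA_real_, ds_dg = NA_real_,
                          ds_dl = NA_real_, abca4_severity = NA_character_,
                          insilico_deleterious = NA) {
  df <- data.frame(
    proband_id = as.character(proband_id), gene = as.character(gene),
    hgvs_c = as.character(hgvs_c), chrom = as.character(chrom),
    pos = as.integer(pos), ref = as.character(ref), alt = as.character(alt),
    consequence = as.character(consequence), gnomad_af = as.numeric(gnomad_af),
    acmg_class = as.integer(acmg_class), zygosity = as.character(zygosity),
    ds_ag = as.numeric(ds_ag), ds_al = as.numeric(ds_al),
    ds_dg = as.numeric(ds_dg), ds_dl = as.numeric(ds_dl),
    abca4_severity = as.character(abca4_severity),
    insilico_deleterious = as.logical(insilico_deleterious),
    stringsAsFactors = FALSE)
  validate_variant_table(df)
}

validate_variant_table <- function(df) {
  missing_cols <- setdiff(variant_table_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("variant table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_cons <- setdiff(unique(df$consequence[!is.na(df$consequence)]),
                      consequence_levels())
  if (length(bad_cons) > 0) {
    stop("unknown consequence label(s): ", paste(bad_cons, collapse = ", "),
         call. = FALSE)
  }
  af <- df$gnomad_af
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop("gnomad_af outside [0, 1]", call. = FALSE)
  }
  cls <- df$acmg_class
  if (any(!is.na(cls) & !(cls %in% 1:5))) {
    stop("acmg_class must be 1..5 or NA (unknown)", call. = FALSE)
  }
  bad_zyg <- setdiff(unique(df$zygosity[!is.na(df$zygosity)]),
                     c("het", "hom", "hemi"))
  if (length(bad_zyg) > 0) {
    stop("unknown zygosity: ", paste(bad_zyg, collapse = ", "), call. = FALSE)
  }
  for (dc in c("ds_ag", "ds_al", "ds_dg", "ds_dl")) {
    v <- df[[dc]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      stop(dc, " outside [0, 1]", call. = FALSE)
    }
  }
  sev <- df$abca4_severity
  bad_sev <- setdiff(unique(sev[!is.na(sev)]), severity_levels())
  if (length(bad_sev) > 0) {
    stop("unknown abca4_severity: ", paste(bad_sev, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- unique(c("macpen_variants", class(df)))
  df
}

#' An empty variant table with the canonical columns
#' @return zero-row `macpen_variants` data.frame
#' @export
empty_variant_table <- function() {
  validate_variant_table(data.frame(
    proband_id = character(), gene = character(), hgvs_c = character(),
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), consequence = character(), gnomad_af = numeric(),
    acmg_class = integer(), zygosity = character(), ds_ag = numeric(),
    ds_al = numeric(), ds_dg = numeric(), ds_dl = numeric(),
    abca4_severity = character(), insilico_deleterious = logical(),
    stringsAsFactors = FALSE))
}

# Gene table -----------------------------------------------------------------

#' Read the gene to inheritance-mode table
#'
#' One row per panel gene: HGNC symbol, inheritance mode (AR/AD/XL/MT) and
#' optional free-text associated phenotypes.
#'
#' @param path TSV with header columns `gene`, `inheritance` and optionally
#'   `phenotypes`
#' @return data.frame with one row per gene
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene", "inheritance") %in% names(df))) {
    stop("gene table must have columns `gene` and `inheritance`",
         call. = FALSE)
  }
  bad <- setdiff(unique(df$inheritance), inheritance_levels())
  if (length(bad) > 0) {
    stop("unknown inheritance token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dup <- df$gene[duplicated(df$gene)]
  if (length(dup) > 0) {
    stop("duplicated gene symbol(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!"phenotypes" %in% names(df)) df$phenotypes <- NA_character_
  df[, c("gene", "inheritance", "phenotypes")]
}

#' Build a gene table in code
#'
#' @param gene HGNC symbols
#' @param inheritance inheritance modes, one of [inheritance_levels()]
#' @param phenotypes optional free-text labels
#' @return data.frame as from [read_gene_table()]
#' @export
gene_table <- function(gene, inheritance, phenotypes = NA_character_) {
  df <- data.frame(gene = as.character(gene),
                   inheritance = as.character(inheritance),
                   phenotypes = as.character(phenotypes),
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$inheritance), inheritance_levels())
  if (length(bad) > 0) {
    stop("unknown inheritance token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$gene) > 0) stop("duplicated gene symbol(s)", call. = FALSE)
  df
}

# VCF input ------------------------------------------------------------------

#' Default mapping of variant-table fields to VCF INFO keys
#'
#' Annotation pipelines differ in how they name INFO fields; the reader takes
#' an explicit mapping so any convention can be consumed. `gene`, `gnomad_af`
#' and `acmg_class` are required to exist in the header; the rest are
#' optional. The splice field holds the four SpliceAI deltas as
#' `AG|AL|DG|DL`.
#'
#' @param gene,cdna,consequence,gnomad_af,acmg_class,splice,severity,insilico
#'   INFO key names
#' @return named list usable as `annotation_spec`
#' @export
annotation_spec <- function(gene = "GENE", cdna = "CDNA", consequence = "CSQ",
                            gnomad_af = "GAF", acmg_class = "ACMG",
                            splice = "SPAI", severity = "SEV",
                            insilico = "ISD") {
  list(gene = gene, cdna = cdna, consequence = consequence,
       gnomad_af = gnomad_af, acmg_class = acmg_class, splice = splice,
       severity = severity, insilico = insilico)
}

# pick the per-alt element of a comma-separated INFO value; recycle a scalar
info_for_alt <- function(value, alt_index, n_alt) {
  if (is.na(value) || value == ".") return(NA_character_)
  parts <- strsplit(value, ",", fixed = TRUE)[[1]]
  out <- if (length(parts) == n_alt) parts[alt_index] else parts[1]
  if (out == ".") NA_character_ else out
}

#' Read an annotated multi-sample VCF into a variant table
#'
#' Multi-allelic records are decomposed into one row per sample x alt allele.
#' Missing annotations (`.`) become `NA`, never 0. Zygosity is derived from
#' the GT field: one copy of the alt among two alleles = het, two copies =
#' hom, a haploid call = hemi.
#'
#' @param path VCF 4.x file
#' @param spec field-name mapping from [annotation_spec()]
#' @return `macpen_variants` data.frame (zero rows for a sample-less VCF)
#' @export
read_annotated_vcf <- function(path, spec = annotation_spec()) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF `", path, "`: ",
                                           conditionMessage(e), call. = FALSE))
  meta <- vcf@meta
  required <- c(spec$gene, spec$gnomad_af, spec$acmg_class)
  declared <- unlist(regmatches(meta, regexec("##INFO=<ID=([^,]+)", meta)))
  declared <- declared[!startsWith(declared, "##INFO")]
  for (key in required) {
    if (!key %in% declared) {
      stop("required annotation `", key, "` not declared in VCF header",
           call. = FALSE)
    }
  }
  fix <- vcf@fix
  n_samples <- ncol(vcf@gt) - 1L
  if (is.null(n_samples) || is.na(n_samples) || n_samples < 1) {
    return(empty_variant_table())
  }
  samples <- colnames(vcf@gt)[-1]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  info <- lapply(spec, function(key) {
    v <- tryCatch(vcfR::extract.info(vcf, element = key),
                  error = function(e) NULL)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else v
  })

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    n_alt <- length(alts)
    for (a in seq_len(n_alt)) {
      spl <- info_for_alt(info$splice[i], a, n_alt)
      ds <- rep(NA_real_, 4)
      if (!is.na(spl)) {
        parts <- suppressWarnings(as.numeric(strsplit(spl, "|", fixed = TRUE)[[1]]))
        if (length(parts) == 4) ds <- parts
      }
      for (s in seq_len(n_samples)) {
        g <- gt[i, s]
        if (is.na(g)) next
        alleles <- strsplit(g, "[/|]")[[1]]
        n_copies <- sum(alleles == as.character(a))
        if (n_copies == 0) next
        zyg <- if (length(alleles) == 1) "hemi"
               else if (n_copies == 2) "hom" else "het"
        af_chr <- info_for_alt(info$gnomad_af[i], a, n_alt)
        cls_chr <- info_for_alt(info$acmg_class[i], a, n_alt)
        isd_chr <- info_for_alt(info$insilico[i], a, n_alt)
        rows[[length(rows) + 1L]] <- data.frame(
          proband_id = samples[s],
          gene = info_for_alt(info$gene[i], a, n_alt),
          hgvs_c = info_for_alt(info$cdna[i], a, n_alt),
          chrom = fix[i, "CHROM"],
          pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[a],
          consequence = info_for_alt(info$consequence[i], a, n_alt),
          gnomad_af = suppressWarnings(as.numeric(af_chr)),
          acmg_class = suppressWarnings(as.integer(cls_chr)),
          zygosity = zyg,
          ds_ag = ds[1], ds_al = ds[2], ds_dg = ds[3], ds_dl = ds[4],
          abca4_severity = info_for_alt(info$severity[i], a, n_alt),
          insilico_deleterious = if (is.na(isd_chr)) NA else isd_chr %in% c("1", "TRUE", "true"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty_variant_table())
  validate_variant_table(do.call(rbind, rows))
}

# VCF output (synthetic cohorts) ---------------------------------------------

#' Write a cohort variant table as an annotated multi-sample VCF
#'
#' Plain-text VCF 4.2 with one row per site and per-sample GT columns, and
#' annotations in the INFO keys of [annotation_spec()]. Output is
#' deterministic (sites sorted by chrom/pos/alt, samples sorted by id) so a
#' rerun with the same inputs is byte-identical.
#'
#' @param variants `macpen_variants` table (all probands)
#' @param samples character vector of all sample ids to emit (a proband with
#'   no variant rows still gets a genotype column of reference calls)
#' @param path output file
#' @param spec INFO key mapping
#' @return `path`, invisibly
#' @export
write_cohort_vcf <- function(variants, samples, path, spec = annotation_spec()) {
  samples <- sort(unique(as.character(samples)))
  fmt <- function(x) ifelse(is.na(x), ".", as.character(x))
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  sites <- unique(variants[, c("chrom", "pos", "ref", "alt", "gene", "hgvs_c",
                               "consequence", "gnomad_af", "acmg_class",
                               "ds_ag", "ds_al", "ds_dg", "ds_dl",
                               "abca4_severity", "insilico_deleterious")])
  sites <- sites[order(sites$chrom, sites$pos, sites$alt), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", spec$gene),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"HGVS cDNA\">", spec$cdna),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Consequence\">", spec$consequence),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"Population allele frequency\">", spec$gnomad_af),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"ACMG class\">", spec$acmg_class),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"SpliceAI deltas AG|AL|DG|DL\">", spec$splice),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"ABCA4 severity category\">", spec$severity),
    sprintf("##INFO=<ID=%s,Number=1,Type=Integer,Description=\"Deleterious in-silico support\">", spec$insilico),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- character(nrow(sites))
  vkey <- key(variants)
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    spai <- if (all(is.na(c(s$ds_ag, s$ds_al, s$ds_dg, s$ds_dl)))) "." else
      paste(fmt(c(s$ds_ag, s$ds_al, s$ds_dg, s$ds_dl)), collapse = "|")
    info <- paste(c(
      paste0(spec$gene, "=", fmt(s$gene)),
      paste0(spec$cdna, "=", fmt(s$hgvs_c)),
      paste0(spec$consequence, "=", fmt(s$consequence)),
      paste0(spec$gnomad_af, "=", fmt(s$gnomad_af)),
      paste0(spec$acmg_class, "=", fmt(s$acmg_class)),
      paste0(spec$splice, "=", spai),
      paste0(spec$severity, "=", fmt(s$abca4_severity)),
      paste0(spec$insilico, "=",
             fmt(if (is.na(s$insilico_deleterious)) NA else as.integer(s$insilico_deleterious)))),
      collapse = ";")
    carriers <- variants[vkey == key(s), c("proband_id", "zygosity")]
    gt <- rep("0/0", length(samples))
    names(gt) <- samples
    gt[carriers$proband_id[carriers$zygosity == "het"]] <- "0/1"
    gt[carriers$proband_id[carriers$zygosity == "hom"]] <- "1/1"
    gt[carriers$proband_id[carriers$zygosity == "hemi"]] <- "1"
    body[i] <- paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", info,
                       "GT", gt), collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

# Results output -------------------------------------------------------------

#' Write verdicts and penetrance estimates to a results directory
#'
#' Emits `verdicts.tsv` (one row per proband, deterministic column order),
#' `penetrance.tsv` and `rationale.json` (rule identifiers fired per
#' proband). [read_results()] reproduces the records exactly.
#'
#' @param verdicts data.frame from [assign_verdicts()]
#' @param estimates data.frame of penetrance estimates (may be `NULL`)
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_results <- function(verdicts, estimates = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcols <- c("proband_id", "status", "causal_gene", "multi_gene", "rationale")
  v <- verdicts[, vcols, drop = FALSE]
  utils::write.table(v, file.path(dir, "verdicts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  rat <- lapply(seq_len(nrow(v)), function(i)
    strsplit(v$rationale[i], ",", fixed = TRUE)[[1]])
  names(rat) <- v$proband_id
  jsonlite::write_json(rat, file.path(dir, "rationale.json"), pretty = TRUE)
  if (!is.null(estimates) && nrow(estimates) > 0) {
    utils::write.table(estimates, file.path(dir, "penetrance.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
  } else {
    utils::write.table(
      data.frame(genotype = character(), observed_count = integer(),
                 cohort_n = integer(), p_x_given_d = numeric(),
                 prevalence = numeric(), p_x = numeric(),
                 penetrance = numeric(), flag = character()),
      file.path(dir, "penetrance.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, na = "NA")
  }
  invisible(dir)
}

#' Read back a results directory written by [write_results()]
#'
#' @param dir results directory
#' @return list with `verdicts` and `penetrance` data.frames
#' @export
read_results <- function(dir) {
  verdicts <- utils::read.delim(
    file.path(dir, "verdicts.tsv"), stringsAsFactors = FALSE,
    colClasses = c(proband_id = "character", status = "character",
                   causal_gene = "character", multi_gene = "logical",
                   rationale = "character"))
  penetrance <- utils::read.delim(file.path(dir, "penetrance.tsv"),
                                  stringsAsFactors = FALSE)
  list(verdicts = verdicts, penetrance = penetrance)
}
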