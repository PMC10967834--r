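# ABCA4 allele-severity grammar ----------------------------------------------
#
# ABCA4 alleles are graded on an ordered scale of residual protein activity
# (no_effect < mild < mild_moderately_severe < moderately_severe < severe).
# Two variants on the same haplotype collapse to the more severe of the two;
# a genotype verdict is then read off the pair of allele severities.

#' Combine the severities of two variants in cis
#'
#' When two variants are (presumed) on the same allele, the allele takes the
#' more severe of the two categories: the join on the severity lattice
#' (commutative, associative, idempotent).
#'
#' @param sev_a,sev_b severity labels or ordered factors
#' @return severity ordered factor (length = common length of inputs)
#' @export
combine_cis_severity <- function(sev_a, sev_b) {
  a <- severity(as.character(sev_a))
  b <- severity(as.character(sev_b))
  if (anyNA(a) || anyNA(b)) stop("both severities must be defined", call. = FALSE)
  severity(ifelse(as.integer(a) >= as.integer(b),
                  as.character(a), as.character(b)))
}

#' Band a splice-assay result into a severity category
#'
#' An in vitro splice assay quantifies the percentage of wild-type RNA a
#' variant allele still produces. The mild band is >40% and <80% WT RNA.
#' Results at or above 80% are classified `no_effect` and at or below 40%
#' `severe`; both outer bands are extrapolations from the mild band's
#' endpoints and the returned value carries an `inferred_band` attribute
#' marking them. Band edges are configurable.
#'
#' @param pct_wt percentage of wild-type RNA remaining, 0-100
#' @param mild_lower,mild_upper open-interval bounds of the mild band
#' @return severity ordered factor with attribute `inferred_band` (logical)
#' @export
classify_splice_result <- function(pct_wt, mild_lower = 40, mild_upper = 80) {
  if (any(is.na(pct_wt) | pct_wt < 0 | pct_wt > 100)) {
    stop("pct_wt must lie in [0, 100]", call. = FALSE)
  }
  lab <- ifelse(pct_wt > mild_lower & pct_wt < mild_upper, "mild",
                ifelse(pct_wt >= mild_upper, "no_effect", "severe"))
  out <- severity(lab)
  attr(out, "inferred_band") <- lab != "mild"
  out
}

#' Splice-assay result record
#'
#' Captures the quantified output of a midigene/minigene splice assay:
#' percent wild-type RNA remaining plus the aberrant products. Products
#' below 15% of total RNA are excluded from reporting.
#'
#' @param variant HGVS cDNA string
#' @param pct_wt percent wild-type RNA, 0-100
#' @param aberrant_products optional data.frame with columns `description`
#'   and `percentage`
#' @param min_product_pct reporting floor for aberrant products (default 15)
#' @return list of class `macpen_splice_assay` with the banded severity
#' @export
splice_assay_result <- function(variant, pct_wt, aberrant_products = NULL,
                                min_product_pct = 15) {
  stop_if_not_scalar_number(pct_wt, "pct_wt", 0, 100)
  if (!is.null(aberrant_products)) {
    aberrant_products <-
      aberrant_products[aberrant_products$percentage > min_product_pct, ,
                        drop = FALSE]
  }
  sev <- classify_splice_result(pct_wt)
  structure(list(variant = variant, pct_wt = pct_wt,
                 aberrant_products = aberrant_products,
                 severity = as.character(sev),
                 inferred_band = attr(sev, "inferred_band")),
            class = "macpen_splice_assay")
}

#' Genotype verdict from a pair of ABCA4 allele severities
#'
#' Reads the solved status off two allele severities (each already
#' cis-combined), for alleles in trans or presumed trans. Rules:
#' \itemize{
#'   \item an allele with no functional effect contributes nothing: the
#'     genotype is effectively mono-allelic and stays `unsolved`;
#'   \item mild + mild: `unsolved` (a mild hypomorph needs a more severe
#'     counter-allele to be penetrant);
#'   \item a reduced-penetrance mild allele (e.g. c.5882G>A) opposite a
#'     mild-moderately severe, moderately severe or severe allele in a
#'     STGD1 proband: `possibly_solved`; outside a STGD1 phenotype, or with
#'     a milder partner: `unsolved`;
#'   \item ordinary mild + severe: `very_likely_solved` (mild hypomorphs are
#'     penetrant in trans with a severe allele); ordinary mild +
#'     mild-moderately/moderately severe: `possibly_solved`;
#'   \item moderately severe/severe + moderately severe/severe:
#'     `very_likely_solved`; mild-moderately severe opposite moderately
#'     severe or severe likewise; mild-moderately severe twice:
#'     `possibly_solved`.
#' }
#' The rule is symmetric in the two alleles.
#'
#' @param sev_a,sev_b allele severity labels (post cis-combination)
#' @param phenotype proband phenotype label; `"STGD1"` enables the
#'   reduced-penetrance mild rule
#' @param reduced_penetrance logical length 2: is each allele's mild variant
#'   on the reduced-penetrance list?
#' @param phase `"trans"` or `"presumed_trans"`; `"cis"` is an error (combine
#'   with [combine_cis_severity()] first)
#' @return list with `status` and `rule` (identifier of the rule fired)
#' @export
abca4_genotype_verdict <- function(sev_a, sev_b, phenotype = NA_character_,
                                   reduced_penetrance = c(FALSE, FALSE),
                                   phase = "presumed_trans") {
  if (identical(phase, "cis")) {
    stop("alleles in cis must be combined with combine_cis_severity() first",
         call. = FALSE)
  }
  a <- as.character(severity(sev_a))
  b <- as.character(severity(sev_b))
  rp <- rep_len(as.logical(reduced_penetrance), 2)
  # canonical order: allele 1 is the less severe one
  ord <- order(match(c(a, b), severity_levels()))
  sev <- c(a, b)[ord]
  rp <- rp[ord]
  lo <- sev[1]; hi <- sev[2]
  at_least_mild_mod <- function(s) {
    match(s, severity_levels()) >= match("mild_moderately_severe",
                                         severity_levels())
  }
  if (lo == "no_effect") {
    return(list(status = "unsolved", rule = "ABCA4_monoallelic_no_effect"))
  }
  if (lo == "mild" && hi == "mild") {
    return(list(status = "unsolved", rule = "ABCA4_mild_mild"))
  }
  if (lo == "mild") {
    if (rp[1]) {
      if (at_least_mild_mod(hi) && identical(phenotype, "STGD1")) {
        return(list(status = "possibly_solved",
                    rule = "ABCA4_reduced_penetrance_mild_STGD1"))
      }
      return(list(status = "unsolved",
                  rule = "ABCA4_reduced_penetrance_mild_unsupported"))
    }
    if (hi == "severe") {
      return(list(status = "very_likely_solved", rule = "ABCA4_mild_severe"))
    }
    return(list(status = "possibly_solved", rule = "ABCA4_mild_moderate"))
  }
  # both alleles >= mild_moderately_severe
  if (lo == "mild_moderately_severe" && hi == "mild_moderately_severe") {
    return(list(status = "possibly_solved", rule = "ABCA4_mildmod_mildmod"))
  }
  list(status = "very_likely_solved", rule = "ABCA4_biallelic_severe")
}

#' Severity lookup table for known ABCA4 variants
#'
#' @param hgvs_c HGVS cDNA strings
#' @param sev severity labels
#' @param reduced_penetrance logical: mild variants whose penetrance depends
#'   on the counter-allele and phenotype (default FALSE)
#' @return data.frame usable as `abca4_severities` in [assign_verdict()]
#' @export
abca4_severity_table <- function(hgvs_c, sev, reduced_penetrance = FALSE) {
  sev <- as.character(severity(sev))
  data.frame(hgvs_c = as.character(hgvs_c), severity = sev,
             reduced_penetrance = rep_len(as.logical(reduced_penetrance),
                                          length(hgvs_c)),
             stringsAsFactors = FALSE)
}
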