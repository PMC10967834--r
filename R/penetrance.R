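# Hardy-Weinberg based penetrance estimation ---------------------------------
#
# For a genotype X observed in a case-ascertained cohort,
#   P(D|X) = P(X|D) * P(D) / P(X)
# where P(X|D) is the genotype frequency among probands, P(D) the disease
# prevalence, and P(X) the Hardy-Weinberg expected genotype frequency in the
# general population from database allele frequencies.

#' Describe a genotype whose population frequency is wanted
#'
#' @param kind `"homozygous"`, `"compound_het"` or `"hemizygous"`
#' @param q1 population allele frequency of the (first) variant
#' @param q2 allele frequency of the second variant (compound het only)
#' @param labels optional HGVS strings naming the variants
#' @return list of class `macpen_genotype_spec`
#' @export
genotype_spec <- function(kind = c("homozygous", "compound_het", "hemizygous"),
                          q1, q2 = NULL, labels = NULL) {
  kind <- match.arg(kind)
  stop_if_not_scalar_number(q1, "q1", 0, 1)
  if (kind == "compound_het") {
    if (is.null(q2)) stop("compound_het requires q2", call. = FALSE)
    stop_if_not_scalar_number(q2, "q2", 0, 1)
    if (!is.null(labels) && length(unique(labels)) < 2) {
      stop("compound_het requires two distinct variants", call. = FALSE)
    }
  }
  structure(list(kind = kind, q1 = q1, q2 = q2, labels = labels),
            class = "macpen_genotype_spec")
}

#' Hardy-Weinberg expected genotype frequency
#'
#' Homozygotes: q^2; compound heterozygotes: 2 q1 q2 (no phase correction);
#' hemizygotes: q.
#'
#' @param spec a [genotype_spec()]
#' @return expected population genotype frequency (fraction)
#' @export
hw_genotype_frequency <- function(spec) {
  stopifnot(inherits(spec, "macpen_genotype_spec"))
  switch(spec$kind,
         homozygous = spec$q1^2,
         compound_het = 2 * spec$q1 * spec$q2,
         hemizygous = spec$q1)
}

#' Estimate the penetrance of a genotype from a case cohort
#'
#' `penetrance = (observed_count / cohort_n) * prevalence / p_x`. Estimates
#' above one are reported raw with the `supra_unity` flag (they signal
#' prevalence misspecification rather than a computational error); a zero
#' expected frequency or zero observations give `not_estimable`.
#'
#' @param observed_count probands in the cohort carrying the genotype
#' @param cohort_n cohort size (the study convention counts all probands,
#'   including QC failures, since ascertainment preceded sequencing)
#' @param prevalence disease prevalence P(D), default 1/5000
#' @param p_x Hardy-Weinberg expected genotype frequency, e.g. from
#'   [hw_genotype_frequency()]
#' @param reduced_threshold penetrance below this is flagged `reduced`
#' @param spec optional [genotype_spec()] carried through for labelling
#' @return list of class `macpen_penetrance`: `observed_count`, `cohort_n`,
#'   `p_x_given_d`, `prevalence`, `p_x`, `penetrance`, `flag`
#' @export
estimate_penetrance <- function(observed_count, cohort_n,
                                prevalence = 1 / 5000, p_x,
                                reduced_threshold = 0.9, spec = NULL) {
  if (!is.numeric(cohort_n) || length(cohort_n) != 1 || cohort_n <= 0) {
    stop("cohort_n must be a positive count", call. = FALSE)
  }
  stopifnot(observed_count >= 0, observed_count <= cohort_n)
  stop_if_not_scalar_number(prevalence, "prevalence", 0, 1)
  if (prevalence == 0) stop("prevalence must be positive", call. = FALSE)
  p_x_given_d <- observed_count / cohort_n
  if (p_x <= 0 || observed_count == 0) {
    pen <- NA_real_
    flag <- "not_estimable"
  } else {
    pen <- p_x_given_d * prevalence / p_x
    flag <- if (pen > 1) "supra_unity"
            else if (pen < reduced_threshold) "reduced" else "complete"
  }
  structure(list(genotype = spec, observed_count = observed_count,
                 cohort_n = cohort_n, p_x_given_d = p_x_given_d,
                 prevalence = prevalence, p_x = p_x, penetrance = pen,
                 flag = flag),
            class = "macpen_penetrance")
}

#' Re-flag a penetrance estimate against a threshold
#'
#' @param estimate a `macpen_penetrance` object
#' @param threshold penetrance below which the flag is `reduced`
#' @return the flag string
#' @export
flag_reduced_penetrance <- function(estimate, threshold = 0.9) {
  stopifnot(inherits(estimate, "macpen_penetrance"))
  pen <- estimate$penetrance
  if (is.na(pen)) return("not_estimable")
  if (pen > 1) return("supra_unity")
  if (pen < threshold) "reduced" else "complete"
}

#' @exportS3Method base::print
print.macpen_penetrance <- function(x, ...) {
  lab <- if (!is.null(x$genotype$labels))
    paste(x$genotype$labels, collapse = "/") else "genotype"
  cat(sprintf("%s: %d/%d probands, P(X)=%.3g, penetrance %s [%s]\n",
              lab, x$observed_count, x$cohort_n, x$p_x,
              if (is.na(x$penetrance)) "NA"
              else sprintf("%.1f%%", 100 * x$penetrance), x$flag))
  invisible(x)
}

#' Allele frequency within the case cohort
#'
#' @param allele_count alleles carrying the variant
#' @param total_alleles total alleles (2 x probands for autosomes; must be
#'   even)
#' @return fraction
#' @export
cohort_allele_frequency <- function(allele_count, total_alleles) {
  if (total_alleles <= 0 || total_alleles %% 2 != 0) {
    stop("total_alleles must be a positive even count", call. = FALSE)
  }
  if (allele_count < 0 || allele_count > total_alleles) {
    stop("allele_count must lie in [0, total_alleles]", call. = FALSE)
  }
  allele_count / total_alleles
}

#' The default list of variants flagged for incomplete penetrance
#'
#' Ten recurrent variants whose population frequency is too high for their
#' observed case frequency under full penetrance: three ABCA4 alleles, three
#' PRPH2 alleles, NMNAT1 c.769G>A, RP1L1 c.133C>T, CDHR1 c.783G>A and CNGB3
#' c.1208G>A.
#'
#' @return data.frame with `gene` and `hgvs_c`
#' @export
default_reduced_penetrance_variants <- function() {
  data.frame(
    gene = c("ABCA4", "ABCA4", "ABCA4", "NMNAT1", "PRPH2", "PRPH2", "PRPH2",
             "RP1L1", "CDHR1", "CNGB3"),
    hgvs_c = c("c.5603A>T", "c.5882G>A", "c.4253+43G>A", "c.769G>A",
               "c.424C>T", "c.514C>T", "c.623G>A", "c.133C>T", "c.783G>A",
               "c.1208G>A"),
    stringsAsFactors = FALSE)
}

#' Count solved probands carrying a flagged reduced-penetrance variant
#'
#' @param verdicts data.frame from [assign_verdicts()]
#' @param variants variant table for the cohort
#' @param flagged data.frame (`gene`, `hgvs_c`) of flagged variants; default
#'   [default_reduced_penetrance_variants()]
#' @return list: `count`, `n_solved`, `share_pct`
#' @export
reduced_penetrance_census <- function(verdicts, variants,
                                      flagged = default_reduced_penetrance_variants()) {
  solved_ids <- verdicts$proband_id[verdicts$status %in% solved_statuses()]
  key <- function(g, h) paste(g, h, sep = "\r")
  flagged_keys <- key(flagged$gene, flagged$hgvs_c)
  hit <- variants$proband_id %in% solved_ids &
    key(variants$gene, variants$hgvs_c) %in% flagged_keys
  count <- length(unique(variants$proband_id[hit]))
  n_solved <- length(solved_ids)
  list(count = count, n_solved = n_solved,
       share_pct = as_percent(count / max(n_solved, 1)))
}

#' Sensitivity of a penetrance estimate to the assumed prevalence
#'
#' The estimator is linear in P(D), and the true prevalence of the disease
#' group is uncertain; this sweeps a grid of prevalences.
#'
#' @param observed_count,cohort_n,p_x as in [estimate_penetrance()]
#' @param prevalences numeric vector of prevalences to evaluate
#' @return data.frame: `prevalence`, `penetrance`, `flag`
#' @export
penetrance_prevalence_sweep <- function(observed_count, cohort_n, p_x,
                                        prevalences = 1 / c(2000, 5000, 10000,
                                                            20000, 40000)) {
  rows <- lapply(prevalences, function(p) {
    est <- estimate_penetrance(observed_count, cohort_n, p, p_x)
    data.frame(prevalence = p, penetrance = est$penetrance, flag = est$flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Seeded bootstrap interval for a penetrance estimate
#'
#' Binomial resampling of the observed genotype count; a plumbing utility,
#' not part of the published estimator.
#'
#' @param observed_count,cohort_n,prevalence,p_x as in [estimate_penetrance()]
#' @param n_boot bootstrap replicates
#' @param conf_level interval coverage
#' @param seed RNG seed
#' @return list: `lower`, `upper`, `estimates`
#' @export
penetrance_bootstrap_ci <- function(observed_count, cohort_n,
                                    prevalence = 1 / 5000, p_x,
                                    n_boot = 2000, conf_level = 0.95,
                                    seed = 1) {
  set.seed(derive_seed(seed, "penetrance_bootstrap"))
  k <- stats::rbinom(n_boot, cohort_n, observed_count / cohort_n)
  est <- (k / cohort_n) * prevalence / p_x
  alpha <- (1 - conf_level) / 2
  q <- stats::quantile(est, c(alpha, 1 - alpha), names = FALSE)
  list(lower = q[1], upper = q[2], estimates = est)
}

#' Reference penetrance table for the two newly flagged variants
#'
#' Recomputes, from their published inputs (database allele frequencies,
#' observed proband counts in a cohort of 1352, prevalence 1/5000), the
#' incomplete-penetrance estimates for CDHR1 c.783G>A (homozygous and
#' compound heterozygous with c.143C>A) and CNGB3 c.1208G>A homozygotes.
#'
#' @param cohort_n cohort size convention (default 1352, all ascertained
#'   probands)
#' @param prevalence assumed disease prevalence
#' @return data.frame: genotype label, inputs, expected Hardy-Weinberg
#'   frequency, penetrance and flag
#' @export
reference_penetrance_table <- function(cohort_n = 1352,
                                       prevalence = 1 / 5000) {
  inputs <- list(
    list(label = "CDHR1 c.783G>A hom",
         spec = genotype_spec("homozygous", q1 = 0.003052,
                              labels = "c.783G>A"),
         observed = 13),
    list(label = "CDHR1 c.783G>A/c.143C>A chet",
         spec = genotype_spec("compound_het", q1 = 0.003052, q2 = 0.000383,
                              labels = c("c.783G>A", "c.143C>A")),
         observed = 2),
    list(label = "CNGB3 c.1208G>A hom",
         spec = genotype_spec("homozygous", q1 = 0.004161,
                              labels = "c.1208G>A"),
         observed = 4))
  rows <- lapply(inputs, function(x) {
    p_x <- hw_genotype_frequency(x$spec)
    est <- estimate_penetrance(x$observed, cohort_n, prevalence, p_x,
                               spec = x$spec)
    data.frame(genotype = x$label, observed_count = x$observed,
               cohort_n = cohort_n, p_x = p_x,
               p_x_pct = round_half_up(100 * p_x, 6),
               penetrance = est$penetrance,
               penetrance_pct = as_percent(est$penetrance),
               flag = est$flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
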