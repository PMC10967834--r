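# Synthetic case-ascertained cohorts -----------------------------------------
#
# Generates fully synthetic inputs with the statistical structure the
# analysis assumes: population genotypes under Hardy-Weinberg, disease
# status under genotype-specific penetrance, case-only proband recruitment
# at a stated prevalence, binomial mtDNA read counts and read-stat tables.
# Variants are simulated independently (no linkage); a cis complex allele
# can be emulated as a single composite variant.

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the study conditions: disease prevalence 1/5000 and a
#' case-ascertained cohort of 1352 probands, drawn from a population large
#' enough to supply them.
#'
#' @param seed global RNG seed; stage generators derive sub-seeds from it
#' @param variants data.frame describing the simulated variants: columns
#'   `gene`, `hgvs_c`, `af`, plus optional annotation columns
#'   (`acmg_class`, `consequence`, `abca4_severity`, `chrom`, `pos`, `ref`,
#'   `alt`)
#' @param genotype_penetrance data.frame mapping causal genotypes to true
#'   penetrance: columns `kind` (`homozygous`/`compound_het`/`hemizygous`),
#'   `hgvs_1`, `hgvs_2` (`NA` unless compound het), `penetrance`
#' @param prevalence_target total disease prevalence in the population
#' @param n_population simulated population size
#' @param n_probands cases recruited into the cohort
#' @param background_rate phenocopy rate for individuals without a causal
#'   genotype; `NULL` (default) solves it so the expected total prevalence
#'   equals `prevalence_target`
#' @param phenotype phenotype label written to the sample sheet
#' @param mtdna data.frame of mtDNA controls: columns `heteroplasmy`,
#'   `depth` (one simulated sample per row)
#' @return list of class `macpen_sim_config`
#' @export
simulation_config <- function(seed = 1,
                              variants,
                              genotype_penetrance,
                              prevalence_target = 1 / 5000,
                              n_population = 1e7,
                              n_probands = 1352,
                              background_rate = NULL,
                              phenotype = "MD",
                              mtdna = NULL) {
  stopifnot(all(c("gene", "hgvs_c", "af") %in% names(variants)))
  stopifnot(all(variants$af >= 0 & variants$af <= 1))
  stopifnot(all(c("kind", "hgvs_1", "penetrance") %in%
                  names(genotype_penetrance)))
  stopifnot(all(genotype_penetrance$penetrance >= 0 &
                  genotype_penetrance$penetrance <= 1))
  if (!"hgvs_2" %in% names(genotype_penetrance)) {
    genotype_penetrance$hgvs_2 <- NA_character_
  }
  stop_if_not_scalar_number(prevalence_target, "prevalence_target", 0, 1)
  cfg <- structure(list(seed = seed, variants = variants,
                        genotype_penetrance = genotype_penetrance,
                        prevalence_target = prevalence_target,
                        n_population = n_population,
                        n_probands = n_probands,
                        background_rate = background_rate,
                        phenotype = phenotype, mtdna = mtdna),
                   class = "macpen_sim_config")
  # validate attainability up front
  solve_background_rate(cfg)
  cfg
}

spec_probability <- function(row, variants) {
  q1 <- variants$af[match(row$hgvs_1, variants$hgvs_c)]
  switch(row$kind,
         homozygous = q1^2,
         compound_het = 2 * q1 * variants$af[match(row$hgvs_2,
                                                   variants$hgvs_c)],
         hemizygous = q1,
         stop("unknown genotype kind: ", row$kind, call. = FALSE))
}

solve_background_rate <- function(config) {
  if (!is.null(config$background_rate)) return(config$background_rate)
  gp <- config$genotype_penetrance
  p_spec <- vapply(seq_len(nrow(gp)),
                   function(i) spec_probability(gp[i, ], config$variants), 1)
  causal_mass <- sum(p_spec * gp$penetrance)
  # phenocopy risk composes with penetrance (1 - (1-pi)(1-bg) for carriers),
  # so the expected prevalence is causal_mass + bg * (1 - causal_mass)
  bg <- (config$prevalence_target - causal_mass) / (1 - causal_mass)
  if (bg < 0) {
    stop("prevalence_target unattainable: causal genotypes alone exceed it",
         call. = FALSE)
  }
  bg
}

#' Simulate population genotypes under Hardy-Weinberg
#'
#' Each variant is drawn independently per individual as an allele count
#' ~ Binomial(2, q), i.e. genotype probabilities q^2 / 2q(1-q) / (1-q)^2.
#'
#' @param config [simulation_config()]
#' @param n_population override of the configured population size
#' @return integer matrix (individuals x variants) of alt allele counts,
#'   columns named by HGVS string
#' @export
simulate_population <- function(config, n_population = config$n_population) {
  set.seed(derive_seed(config$seed, "population"))
  n <- as.integer(n_population)
  g <- vapply(config$variants$af,
              function(q) stats::rbinom(n, 2L, q),
              integer(n))
  g <- matrix(as.integer(g), nrow = n)
  colnames(g) <- config$variants$hgvs_c
  g
}

match_causal_spec <- function(genotypes, config) {
  gp <- config$genotype_penetrance
  spec_idx <- rep(NA_integer_, nrow(genotypes))
  for (i in rev(seq_len(nrow(gp)))) {   # earlier rows take priority
    v1 <- genotypes[, gp$hgvs_1[i]]
    hit <- switch(gp$kind[i],
                  homozygous = v1 == 2L,
                  compound_het = v1 == 1L & genotypes[, gp$hgvs_2[i]] == 1L,
                  hemizygous = v1 >= 1L)
    spec_idx[hit] <- i
  }
  spec_idx
}

#' Assign disease status under genotype-specific penetrance
#'
#' Individuals carrying a causal genotype are affected with that genotype's
#' penetrance (first matching row of `genotype_penetrance` wins), composed
#' independently with the background (phenocopy) risk that affects everyone:
#' carriers are cases with probability `1 - (1 - penetrance)(1 - bg)`,
#' non-carriers with probability `bg`. The background rate is solved so the
#' expected total prevalence matches `prevalence_target`; a zero-penetrance
#' genotype therefore leaves its carriers at exactly the phenocopy risk.
#'
#' @param genotypes matrix from [simulate_population()]
#' @param config [simulation_config()]
#' @return logical vector of disease status, with attribute `causal_spec`
#'   (matched row index of `genotype_penetrance`, `NA` for non-carriers)
#' @export
assign_disease <- function(genotypes, config) {
  set.seed(derive_seed(config$seed, "disease"))
  bg <- solve_background_rate(config)
  spec_idx <- match_causal_spec(genotypes, config)
  pen <- config$genotype_penetrance$penetrance[spec_idx]
  p <- ifelse(is.na(spec_idx), bg, 1 - (1 - pen) * (1 - bg))
  disease <- stats::rbinom(nrow(genotypes), 1L, p) == 1L
  attr(disease, "causal_spec") <- spec_idx
  disease
}

#' Ascertain a case-only proband cohort
#'
#' Uniform sampling without replacement from the affected individuals,
#' emulating case-only recruitment. Emits a sample sheet and an annotated
#' variant table; optionally writes the cohort as an annotated VCF.
#'
#' @param genotypes matrix from [simulate_population()]
#' @param disease logical vector from [assign_disease()]
#' @param config [simulation_config()]
#' @param vcf_path optional path: write the cohort VCF via
#'   [write_cohort_vcf()]
#' @return list: `sample_sheet` (proband_id, phenotype, sex, qc_pass),
#'   `variants` (`macpen_variants` table), `individual_index`
#' @export
ascertain_probands <- function(genotypes, disease, config, vcf_path = NULL) {
  cases <- which(disease)
  if (length(cases) < config$n_probands) {
    stop(sprintf("insufficient cases: %d available, %d requested",
                 length(cases), config$n_probands), call. = FALSE)
  }
  set.seed(derive_seed(config$seed, "ascertainment"))
  picked <- sort(sample(cases, config$n_probands))
  ids <- sprintf("P%06d", seq_along(picked))
  va <- config$variants
  get_col <- function(col, default) {
    if (col %in% names(va)) va[[col]] else rep(default, nrow(va))
  }
  chrom <- get_col("chrom", "1")
  pos <- get_col("pos", NA)
  if (all(is.na(pos))) pos <- seq_len(nrow(va)) * 1000L
  ref <- get_col("ref", "A")
  alt <- get_col("alt", "G")
  rows <- list()
  sub <- genotypes[picked, , drop = FALSE]
  for (j in seq_len(nrow(va))) {
    carriers <- which(sub[, va$hgvs_c[j]] > 0L)
    if (length(carriers) == 0) next
    rows[[length(rows) + 1L]] <- variant_table(
      proband_id = ids[carriers], gene = va$gene[j], hgvs_c = va$hgvs_c[j],
      chrom = chrom[j], pos = pos[j], ref = ref[j], alt = alt[j],
      consequence = get_col("consequence", "missense")[j],
      gnomad_af = va$af[j],
      acmg_class = get_col("acmg_class", NA_integer_)[j],
      zygosity = ifelse(sub[carriers, va$hgvs_c[j]] == 2L, "hom", "het"),
      abca4_severity = get_col("abca4_severity", NA_character_)[j])
  }
  variants <- if (length(rows) > 0) {
    validate_variant_table(do.call(rbind, rows))
  } else {
    empty_variant_table()
  }
  variants <- variants[order(variants$proband_id, variants$gene,
                             variants$hgvs_c), , drop = FALSE]
  rownames(variants) <- NULL
  sheet <- data.frame(proband_id = ids, phenotype = config$phenotype,
                      sex = NA_character_, qc_pass = TRUE,
                      stringsAsFactors = FALSE)
  if (!is.null(vcf_path)) write_cohort_vcf(variants, ids, vcf_path)
  list(sample_sheet = sheet, variants = variants, individual_index = picked)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: population, disease assignment and ascertainment in
#' one call.
#'
#' @inheritParams ascertain_probands
#' @param config [simulation_config()]
#' @param vcf_path optional cohort VCF output path
#' @return as [ascertain_probands()]
#' @export
simulate_cohort <- function(config, vcf_path = NULL) {
  g <- simulate_population(config)
  d <- assign_disease(g, config)
  ascertain_probands(g, d, config, vcf_path = vcf_path)
}

#' Simulate mtDNA pileup counts at known heteroplasmy
#'
#' Alt read counts are Binomial(depth, heteroplasmy), one sample per row of
#' the control design.
#'
#' @param controls data.frame with columns `heteroplasmy` (fractions) and
#'   `depth` (reads); defaults to `config$mtdna` when a config is given
#' @param seed RNG seed
#' @param position coordinate label written on every row
#' @return data.frame: `sample`, `position`, `ref_count`, `alt_count`,
#'   `true_heteroplasmy`
#' @export
simulate_mtdna_counts <- function(controls, seed = 1, position = "m.3243") {
  if (inherits(controls, "macpen_sim_config")) {
    seed <- controls$seed
    controls <- controls$mtdna
  }
  stopifnot(all(controls$depth > 0),
            all(controls$heteroplasmy >= 0 & controls$heteroplasmy <= 1))
  set.seed(derive_seed(seed, "mtdna"))
  alt <- stats::rbinom(nrow(controls), controls$depth, controls$heteroplasmy)
  data.frame(sample = sprintf("MT%03d", seq_len(nrow(controls))),
             position = position,
             ref_count = controls$depth - alt, alt_count = alt,
             true_heteroplasmy = controls$heteroplasmy,
             stringsAsFactors = FALSE)
}

#' Simulate per-sample read statistics
#'
#' Plumbing for pipeline smoke tests: forward/reverse read counts and an
#' average per-probe coverage around the panel's typical 85x.
#'
#' @param n samples
#' @param seed RNG seed
#' @param mean_coverage mean per-probe coverage
#' @param fail_rate share of samples with near-zero coverage (QC failures)
#' @return data.frame consumable by [sample_qc()]
#' @export
simulate_read_stats <- function(n, seed = 1, mean_coverage = 85,
                                fail_rate = 74 / 1352) {
  set.seed(derive_seed(seed, "readstats"))
  cov <- stats::rgamma(n, shape = 20, rate = 20 / mean_coverage)
  failed <- stats::runif(n) < fail_rate
  cov[failed] <- stats::runif(sum(failed), 0, 5)
  fwd <- stats::rpois(n, cov * 17394 / 2) * 2L
  rev <- stats::rpois(n, cov * 17394 / 2) * 2L
  data.frame(sample_id = sprintf("P%06d", seq_len(n)),
             forward_reads = fwd, reverse_reads = rev,
             avg_smmips_coverage = cov, stringsAsFactors = FALSE)
}

# Count-level replicate generator --------------------------------------------

#' Replicate the observed genotype count in ascertained cohorts
#'
#' Exact count-level form of the generative model, used for replicate
#' studies of the penetrance estimator: the number of probands carrying the
#' target genotype is a sufficient statistic, and its distribution under
#' (population Hardy-Weinberg draw) -> (penetrance thinning) ->
#' (case-only sampling without replacement) is
#' Binomial -> Binomial -> hypergeometric. Each replicate errors out if the
#' population yields fewer cases than probands requested.
#'
#' @param spec target [genotype_spec()] (carries the allele frequencies)
#' @param penetrance true penetrance of the target genotype
#' @param prevalence total disease prevalence (background rate is solved
#'   from it)
#' @param n_population population size per replicate
#' @param n_probands cohort size
#' @param n_reps replicates
#' @param seed RNG seed
#' @return integer vector (length `n_reps`) of observed genotype counts
#' @export
simulate_ascertained_counts <- function(spec, penetrance,
                                        prevalence = 1 / 5000,
                                        n_population = 1e7,
                                        n_probands = 1352,
                                        n_reps = 200, seed = 1) {
  stop_if_not_scalar_number(penetrance, "penetrance", 0, 1)
  p_x <- hw_genotype_frequency(spec)
  mass <- p_x * penetrance
  bg <- (prevalence - mass) / (1 - mass)
  if (bg < 0) stop("prevalence unattainable for this genotype/penetrance",
                   call. = FALSE)
  set.seed(derive_seed(seed, "count_replicates"))
  n_x <- stats::rbinom(n_reps, n_population, p_x)
  cases_x <- stats::rbinom(n_reps, n_x, 1 - (1 - penetrance) * (1 - bg))
  cases_other <- stats::rbinom(n_reps, n_population - n_x, bg)
  if (any(cases_x + cases_other < n_probands)) {
    stop("insufficient cases in at least one replicate", call. = FALSE)
  }
  stats::rhyper(n_reps, cases_x, cases_other, n_probands)
}

#' Parameter-recovery study for the penetrance estimator
#'
#' Simulates replicate ascertained cohorts at a known true penetrance and
#' re-estimates it from each, returning the estimates and their Monte Carlo
#' summary.
#'
#' @inheritParams simulate_ascertained_counts
#' @return list: `estimates`, `mean`, `mc_se` (standard error of the mean),
#'   `true_penetrance`
#' @export
recover_penetrance <- function(spec, penetrance, prevalence = 1 / 5000,
                               n_population = 1e7, n_probands = 1352,
                               n_reps = 200, seed = 1) {
  k <- simulate_ascertained_counts(spec, penetrance, prevalence,
                                   n_population, n_probands, n_reps, seed)
  p_x <- hw_genotype_frequency(spec)
  est <- (k / n_probands) * prevalence / p_x
  list(estimates = est, mean = mean(est),
       mc_se = stats::sd(est) / sqrt(n_reps),
       true_penetrance = penetrance)
}
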