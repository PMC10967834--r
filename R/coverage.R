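# Read accounting, coverage arithmetic and sample QC -------------------------

#' Mapped read count from forward/reverse read counts
#'
#' Deduplicated paired-end accounting: forward plus reverse reads, divided by
#' two. The exact value is returned; set `as_integer = TRUE` for the
#' half-up-rounded integer report.
#'
#' @param forward,reverse non-negative read counts
#' @param as_integer round half-up to an integer count
#' @return numeric (or integer) vector
#' @export
mapped_read_count <- function(forward, reverse, as_integer = FALSE) {
  if (any(forward < 0) || any(reverse < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  x <- (forward + reverse) / 2
  if (as_integer) as.integer(round_half_up(x)) else x
}

#' Per-nucleotide fold coverage from per-probe coverage
#'
#' Each nucleotide in the capture design is tiled by several probes, so the
#' per-nucleotide coverage is the average per-probe coverage times the
#' probes per nucleotide (eight in this panel design).
#'
#' @param avg_smmips_coverage average fold coverage per probe
#' @param smmips_per_nt probes tiling each nucleotide (default 8)
#' @return fold coverage per nucleotide
#' @export
per_nucleotide_coverage <- function(avg_smmips_coverage, smmips_per_nt = 8) {
  if (any(avg_smmips_coverage < 0) || any(smmips_per_nt < 0)) {
    stop("coverage inputs must be non-negative", call. = FALSE)
  }
  avg_smmips_coverage * smmips_per_nt
}

#' Per-sample sequencing QC
#'
#' Samples below the average per-probe coverage floor fail QC, receive a
#' `failed` verdict and are excluded from the diagnostic-yield denominator.
#' The floor is a configurable stand-in: the underlying failure mode
#' (insufficient or degraded DNA) has no published numeric cutoff.
#'
#' @param stats data.frame with columns `sample_id`, `forward_reads`,
#'   `reverse_reads`, `avg_smmips_coverage`
#' @param min_avg_coverage QC floor on average per-probe coverage (default 10)
#' @return `stats` with added `mapped_reads` and `qc_pass` columns
#' @export
sample_qc <- function(stats, min_avg_coverage = 10) {
  stats$mapped_reads <- mapped_read_count(stats$forward_reads,
                                          stats$reverse_reads)
  stats$qc_pass <- stats$avg_smmips_coverage >= min_avg_coverage
  stats
}
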