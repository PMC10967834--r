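#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("round half up") rounding, used for all reported percentages
#' so that printed shares are reproducible regardless of the platform's
#' banker's rounding.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a percentage rounded half-up
#'
#' @param x proportion in \[0, 1\]
#' @param digits decimal places of the percentage (default 1)
#' @return numeric percentage
#' @export
as_percent <- function(x, digits = 1) {
  round_half_up(100 * x, digits)
}

# deterministic sub-seed derivation: one user-facing seed, distinct
# reproducible streams per stage (kept below 2^31 - 1)
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(seed) * 48271 + h) %% 2147483563L) + 1L
}

stop_if_not_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
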