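#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), the convention used for
#' the printed cohort percentages. Base R's \code{round()} rounds half to
#' even, which differs at exact .5 ties.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Canonical variant key
#'
#' Variant identity throughout the package is the tuple
#' (chrom, pos, ref, alt), serialised as \code{"chrom:pos:ref:alt"}.
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort mean of a per-proband count
#'
#' The descriptive mean used in cohort reports: total count divided by the
#' number of probands, rounded to the printed precision.
#'
#' @param total total count over the cohort.
#' @param n_probands number of probands (denominator; empty probands count).
#' @param digits decimal places (default 2, the printed convention).
#' @return numeric scalar.
#' @export
cohort_mean <- function(total, n_probands, digits = 2) {
  stopifnot(n_probands > 0)
  round_half_up(total / n_probands, digits)
}

#' Defect-type percentage
#'
#' Percentage of probands with a given defect label, rounded half-up to one
#' decimal, matching the printed cohort tables.
#'
#' @param count probands with the defect.
#' @param n_probands cohort size.
#' @return percentage on the 0-100 scale.
#' @export
defect_percentage <- function(count, n_probands) {
  stopifnot(n_probands > 0, count >= 0, count <= n_probands)
  round_half_up(100 * count / n_probands, 1)
}
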