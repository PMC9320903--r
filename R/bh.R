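#' Benjamini-Hochberg step-up adjustment
#'
#' Computes BH q-values: q_(i) = min_{j >= i} m * p_(j) / j, capped at 1,
#' returned in the input order. Output is invariant to permutation of the
#' input (up to the matching permutation), satisfies q >= p elementwise,
#' and is non-decreasing in p-rank. NAs are ignored (returned as NA) and
#' do not count towards m.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0,1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(q)
  o <- order(p[ok])
  ranked <- p[ok][o] * m / seq_len(m)
  qq <- rev(cummin(rev(ranked)))
  qq <- pmin(qq, 1)
  q[ok[o]] <- qq
  q
}
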