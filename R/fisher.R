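#' Two-sided Fisher exact test for pooled allele counts
#'
#' Exact p for the 2x2 table `(ref_a, alt_a; ref_b, alt_b)` with both
#' margins fixed, two-sided by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities of all tables no more probable than the
#' observed one (up to a small relative tolerance against ties lost to
#' floating point). Vectorised over records; totals of a few hundred
#' reads enumerate in microseconds.
#'
#' @param ref_a,alt_a Reference and alternate read counts in Pool A.
#' @param ref_b,alt_b Reference and alternate read counts in Pool B.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact_p(5, 5, 5, 5)   # 1
#' fisher_exact_p(10, 0, 0, 10) # strongly unbalanced table
#' @export
fisher_exact_p <- function(ref_a, alt_a, ref_b, alt_b) {
  n <- length(ref_a)
  stopifnot(length(alt_a) == n, length(ref_b) == n, length(alt_b) == n)
  if (any(c(ref_a, alt_a, ref_b, alt_b) < 0)) abort("counts must be >= 0.")
  tot <- ref_a + alt_a + ref_b + alt_b
  if (any(tot == 0)) abort("all-zero table has no Fisher p-value.")
  m <- alt_a + alt_b      # total alt (white balls)
  nn <- ref_a + ref_b     # total ref (black balls)
  k <- ref_a + alt_a      # Pool A depth (draws)
  vapply(seq_len(n), function(i) {
    lo <- max(0L, k[i] - nn[i])
    hi <- min(k[i], m[i])
    d <- dhyper(lo:hi, m[i], nn[i], k[i])
    d_obs <- dhyper(alt_a[i], m[i], nn[i], k[i])
    min(sum(d[d <= d_obs * (1 + 1e-7)]), 1)
  }, numeric(1))
}
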