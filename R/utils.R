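#' Harmonic number
#'
#' `H(n) = sum_{i=1}^{n} 1/i`, the Watterson normalizer: under neutrality the
#' expected number of segregating sites in a sample of `n + 1` chromosomes is
#' `theta * L * H(n)`, and the expected singleton fraction of the spectrum is
#' `1 / H(n)`.
#'
#' @param n Non-negative integer.
#' @return The n-th harmonic number (0 for n = 0).
#' @examples
#' 1 / harmonicNumber(29999)  # neutral singleton fraction at m = 30,000
#' @export
harmonicNumber <- function(n) {
  n <- as.integer(n)
  stopifnot(length(n) == 1L, n >= 0L)
  if (n == 0L) return(0)
  sum(1 / seq_len(n))
}

complementBase <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")[b])
}

#' Two-sided Fisher exact p by hypergeometric point-probability rule
#'
#' Internal wrapper around [stats::fisher.test] used by the divergence
#' contrasts; two-sided p is the sum of all tables with fixed margins whose
#' probability does not exceed the observed table's (the point-probability
#' convention).
#'
#' @param tab 2x2 integer matrix.
#' @return p-value.
#' @keywords internal
fisherTwoSided <- function(tab) {
  stats::fisher.test(round(tab))$p.value
}
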