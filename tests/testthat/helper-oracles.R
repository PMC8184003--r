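# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration and hand formulas only.

# Two-sided Fisher p by exhaustive enumeration over all 2x2 tables with the
# observed margins (point-probability rule).
enumFisherP <- function(tab) {
  tab <- round(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  probs <- exp(logp)
  pObs <- probs[match(tab[1, 1], xs)]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Pearson chi-squared for a 2x2 table by the closed-form N(ad-bc)^2 / products
chi2Hand <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Downsampling projection by explicit enumeration of all m-subsets of the
# an chromosomes (ac of which carry the alternate allele). Feasible for
# an <= ~15.
enumProjection <- function(ac, an, m) {
  chroms <- c(rep(1, ac), rep(0, an - ac))
  subsets <- utils::combn(an, m)
  counts <- apply(subsets, 2, function(ix) sum(chroms[ix]))
  tabulate(counts + 1L, nbins = m + 1L) / ncol(subsets)
}

# Monte-Carlo projection: repeated random subsampling without replacement
sampleProjectionOracle <- function(ac, an, m, nDraws = 10000L) {
  draws <- replicate(nDraws, sum(sample(c(rep(1L, ac), rep(0L, an - ac)), m)))
  tabulate(draws + 1L, nbins = m + 1L) / nDraws
}

# Minimal VCF writer for hand-built fixtures (header + given body lines)
writeToyVcf <- function(bodyLines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"AC\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"AN\">",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=RF,Description=\"failed random forest\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(header, bodyLines), path)
  path
}

writeToyCoverage <- function(df, path = tempfile(fileext = ".tsv")) {
  names(df) <- c("chrom", "pos", "frac_over_15x")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Small two-exon lncRNA gene used throughout: exons 101-200 and 301-400
toyGene <- function(biotype = "lncRNA", strand = "+") {
  GeneModel("toy_gene", "toy_tx", "synth1", c(101L, 301L), c(200L, 400L),
            strand = strand, biotype = biotype)
}

toyRepeats <- function() {
  gr <- GenomicRanges::GRanges("synth1", IRanges::IRanges(
    start = c(101L, 350L), end = c(160L, 360L)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    repeat_name = c("LTR7", "AluY"), repeat_class = c("LTR/ERV1", "SINE/Alu"))
  gr
}
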