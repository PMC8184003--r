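#' Hypergeometric downsampling projection of one site
#'
#' Converts a site observed with `ac` alternate alleles among `an` called
#' chromosomes into its expected contribution to a spectrum over a common
#' sample size `m`: entry j (j = 0..m) is the probability of drawing j
#' alternate alleles in `m` draws without replacement from the `an`
#' chromosomes. This balances small differences in the number of chromosomes
#' called at each polymorphic site. The vector sums to one, and its mean
#' preserves the allele frequency: `sum(j * p_j) = m * ac / an`.
#'
#' @param ac Alternate-allele count, `0 < ac < an`.
#' @param an Number of called chromosomes.
#' @param m Target sample size, `m <= an`.
#' @return Numeric vector of length `m + 1` (indices 0..m).
#' @examples
#' projectSite(2, 4, 2)  # 1/6, 2/3, 1/6
#' @export
projectSite <- function(ac, an, m) {
  ac <- as.integer(ac); an <- as.integer(an); m <- as.integer(m)
  stopifnot(length(ac) == 1L, ac > 0L, ac < an, m >= 1L, m <= an)
  stats::dhyper(0:m, ac, an - ac, m)
}

#' Build a downsampled site-frequency spectrum
#'
#' Sums the per-site hypergeometric projections over all sites of a stratum.
#' Mass projected to allele count 0 or m accumulates into the
#' dropped-monomorphic-mass slot; sites with `an < m` cannot be projected up
#' and are excluded (their number is recorded in the object so the exclusion
#' is auditable). The default deterministic expectation mode has lower
#' variance than subsampling; `method = "sampled"` instead draws one random
#' hypergeometric subsample per site, which is the independent route used to
#' cross-check the expectation in tests.
#'
#' @param sites An [SNVSites-class] object (typically restricted to one
#'   stratum).
#' @param m Projected sample size (default 30,000 chromosomes).
#' @param method `"expected"` (default) or `"sampled"`.
#' @param seed Seed for `method = "sampled"`.
#' @return A [SiteFreqSpectrum-class] object.
#' @export
buildSFS <- function(sites, m = 30000L, method = c("expected", "sampled"),
                     seed = NULL) {
  stopifnot(is(sites, "SNVSites"))
  method <- match.arg(method)
  m <- as.integer(m)
  tab <- siteTable(sites)
  tab <- tab[tab$ac > 0L & tab$ac < tab$an, , drop = FALSE]
  usable <- tab$an >= m
  nExcluded <- sum(!usable)
  tab <- tab[usable, , drop = FALSE]
  acc <- numeric(m + 1L)
  if (method == "expected") {
    for (i in seq_len(nrow(tab))) {
      acc <- acc + projectSite(tab$ac[i], tab$an[i], m)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    if (nrow(tab) > 0) {
      draws <- stats::rhyper(nrow(tab), tab$ac, tab$an - tab$ac, m)
      acc <- tabulate(draws + 1L, nbins = m + 1L)
    }
  }
  new("SiteFreqSpectrum", m = m, bins = acc[2:m],
      nSitesUsed = as.numeric(nrow(tab)),
      droppedMass = acc[1] + acc[m + 1L],
      nExcludedLowAN = as.integer(nExcluded))
}

#' Singleton summary of a spectrum
#'
#' The singleton fraction — bin j = 1 of the projected spectrum divided by
#' its total segregating mass — is the left-shift statistic: deleterious
#' alleles held at low frequency by purifying selection inflate it above the
#' neutral expectation `1 / H(m - 1)`.
#'
#' @param sfs A [SiteFreqSpectrum-class] object.
#' @return List with `singleton_mass`, `total_mass` and `fraction`.
#' @export
singletonFraction <- function(sfs) {
  stopifnot(is(sfs, "SiteFreqSpectrum"))
  total <- sum(sfs@bins)
  if (total <= 0) {
    warning("spectrum has no segregating mass; singleton fraction undefined")
    return(list(singleton_mass = 0, total_mass = 0, fraction = NA_real_))
  }
  list(singleton_mass = sfs@bins[1], total_mass = total,
       fraction = sfs@bins[1] / total)
}

#' Chi-squared contrast of singleton fractions
#'
#' Tests whether a target stratum's singleton fraction differs from the
#' neutral expectation carried by a reference spectrum (synonymous sites in
#' the genome-wide application). Projected masses are rounded to integer
#' counts, arranged as a 2x2 singleton / non-singleton by target / reference
#' table, and tested by Pearson's chi-squared with one degree of freedom and
#' no continuity correction. Expected cells below one flag the result but do
#' not suppress it.
#'
#' @param target,reference [SiteFreqSpectrum-class] objects, or lists from
#'   [singletonFraction()].
#' @param alpha Significance level (two-sided, 0.05).
#' @return A [SelTestResult-class].
#' @export
singletonChi2Test <- function(target, reference, alpha = 0.05) {
  getCounts <- function(x) {
    if (is(x, "SiteFreqSpectrum")) x <- singletonFraction(x)
    c(singleton = round(x$singleton_mass),
      other = round(x$total_mass - x$singleton_mass))
  }
  tgt <- getCounts(target)
  ref <- getCounts(reference)
  if (sum(tgt) < 1 || sum(ref) < 1) {
    stop("both groups need total counts >= 1")
  }
  tab <- rbind(target = tgt, reference = ref)
  flags <- character(0)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expd < 1)) {
    flags <- "expected cell count < 1; chi-squared approximation unreliable"
    warning(flags)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  SelTestResult("singleton chi-squared", tab,
                statistic = unname(ht$statistic),
                ratio = (tgt[1] / sum(tgt)) / (ref[1] / sum(ref)),
                pValue = ht$p.value, alpha = alpha, flags = flags)
}

#' Singleton-fraction screen across lncRNA genes
#'
#' For each gene with at least `minSNVs` usable SNVs, builds the projected
#' spectrum of its exonic sites, computes the singleton fraction and tests it
#' against the synonymous-site reference by [singletonChi2Test()]. Per-gene
#' significance is flagged at the unadjusted two-sided `alpha` (matching the
#' per-gene red-tick convention of genome-wide lncRNA screens); a
#' Benjamini-Hochberg-adjusted column is emitted alongside.
#'
#' @param geneSites Named list of [SNVSites-class] objects (exonic SNVs per
#'   gene).
#' @param reference [SNVSites-class] of synonymous (neutral reference) sites.
#' @param conservationClass Optional named character vector
#'   (`"conserved"`/`"other"`) per gene, from [classifyLncrnaConservation()].
#' @param minSNVs Minimum usable SNVs for a gene to enter the screen (50).
#' @param m Projected sample size (30,000).
#' @param alpha Per-gene significance level (0.05).
#' @return `data.frame` with columns gene_id, class, n_snvs,
#'   singleton_fraction, chi2, p, p_bh, significant.
#' @export
lncrnaSingletonScreen <- function(geneSites, reference,
                                  conservationClass = NULL, minSNVs = 50L,
                                  m = 30000L, alpha = 0.05) {
  stopifnot(is.list(geneSites))
  if (!is(reference, "SNVSites") || length(reference) == 0L) {
    stop("reference site set is empty")
  }
  refSfs <- buildSFS(reference, m = m)
  rows <- lapply(names(geneSites), function(g) {
    sfs <- buildSFS(geneSites[[g]], m = m)
    if (sfs@nSitesUsed < minSNVs) return(NULL)
    sf <- singletonFraction(sfs)
    ht <- singletonChi2Test(sfs, refSfs, alpha = alpha)
    data.frame(gene_id = g,
               class = if (!is.null(conservationClass))
                 unname(conservationClass[g]) else NA_character_,
               n_snvs = sfs@nSitesUsed, singleton_fraction = sf$fraction,
               chi2 = ht@statistic, p = ht@pValue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(gene_id = character(0), class = character(0),
                      n_snvs = numeric(0), singleton_fraction = numeric(0),
                      chi2 = numeric(0), p = numeric(0), p_bh = numeric(0),
                      significant = logical(0)))
  }
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$class, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a spectrum as TSV
#'
#' @param sfs A [SiteFreqSpectrum-class].
#' @param path Output path; columns `j` and `expected_count`.
#' @return `path`, invisibly.
#' @export
writeSFS <- function(sfs, path) {
  stopifnot(is(sfs, "SiteFreqSpectrum"))
  utils::write.table(
    data.frame(j = seq_len(sfs@m - 1L), expected_count = sfs@bins),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
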